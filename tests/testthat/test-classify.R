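# Homoeolog classification rules and dominance summaries.

test_that("group-specific expression needs all-zero vs all-expressed", {
    expect_identical(detectSpecific(c(0, 0, 0), c(3, 5, 4)),
                     "specific-to-B")
    expect_identical(detectSpecific(c(0, 0, 0), c(2, 5, 4)), "none")
    expect_identical(detectSpecific(c(0, 0, 1), c(9, 9, 9)), "none")
    expect_identical(detectSpecific(c(4, 3, 6), c(0, 0, 0)),
                     "specific-to-A")
    expect_error(detectSpecific(c(0, 0), c(1, 2, 3)), "same number")
})

test_that("silencing, bias and exclusion rules classify as specified", {
    expect_identical(classifyHomoeolog(c(0, 0, 0), c(5, 7, 6)),
                     "BSB-HES")
    expect_identical(classifyHomoeolog(c(5, 7, 6), c(0, 0, 0)),
                     "TC-HES")
    # ratio boundaries are inclusive
    expect_identical(classifyHomoeolog(c(20, 22, 18), c(10, 11, 9)),
                     "BSB-HEB")   # ratio exactly 2
    expect_identical(classifyHomoeolog(c(10, 11, 9), c(20, 22, 18)),
                     "TC-HEB")    # ratio exactly 0.5
    expect_identical(classifyHomoeolog(c(10, 10, 10), c(10, 10, 10)),
                     "normal")
    # weakly expressed single-sided pairs are excluded, not classified
    expect_identical(classifyHomoeolog(c(0, 0, 0), c(1, 2, 2)),
                     "excluded")
    expect_identical(classifyHomoeolog(c(0, 0, 0), c(0, 0, 0)),
                     "excluded")
    # just inside the boundaries stays normal
    expect_identical(classifyHomoeolog(c(19, 19, 19), c(10, 10, 10)),
                     "normal")
})

test_that("rule precedence between silencing and exclusion is configurable", {
    # with an exclusion floor above the silencing floor the two rules
    # overlap at (0,0,0) vs (3,3,3): silencing-first keeps the HES call,
    # exclusion-first drops the pair
    expect_identical(
        classifyHomoeolog(c(0, 0, 0), c(3, 3, 3), exclusionMean = 4,
                          hesFirst = TRUE), "BSB-HES")
    expect_identical(
        classifyHomoeolog(c(0, 0, 0), c(3, 3, 3), exclusionMean = 4,
                          hesFirst = FALSE), "excluded")
})

test_that("classification postconditions hold on random inputs", {
    set.seed(17)
    bsb <- matrix(rpois(400 * 3, 4), 400, 3)
    tc <- matrix(rpois(400 * 3, 4), 400, 3)
    out <- classifyPairs(bsb, tc)
    expect_identical(nrow(out), 400L)
    expect_true(all(out$category %in%
        c("BSB-HES", "TC-HES", "BSB-HEB", "TC-HEB", "normal",
          "excluded")))
    for (i in seq_len(nrow(out))) {
        # scalar and vectorized paths agree
        expect_identical(out$category[i],
                         classifyHomoeolog(bsb[i, ], tc[i, ]))
        switch(out$category[i],
            "BSB-HES" = expect_true(all(bsb[i, ] == 0) &&
                                    all(tc[i, ] >= 3)),
            "TC-HES" = expect_true(all(tc[i, ] == 0) &&
                                   all(bsb[i, ] >= 3)),
            "BSB-HEB" = expect_gte(out$ratio[i], 2),
            "TC-HEB" = expect_lte(out$ratio[i], 0.5),
            "normal" = expect_true(out$ratio[i] > 0.5 &&
                                   out$ratio[i] < 2),
            "excluded" = expect_true(is.na(out$ratio[i])))
    }
})

test_that("dominance summaries compute totals, percentages and rollups", {
    counts <- matrix(c(4522, 2977, 243, 254, 2070), nrow = 1,
                     dimnames = list("C-Intestine",
                                     c("BSB-HES", "TC-HEB", "TC-HES",
                                       "BSB-HEB", "normal")))
    s <- summarizeDominance(counts)
    expect_identical(s$total, 10066L)
    expect_equal(s$`pct_BSB-HES`, 44.92)
    expect_identical(s$tc_dominance, 4522L + 2977L)
    expect_identical(s$bsb_dominance, 243L + 254L)
    # a single normal record is 100%
    rec <- data.frame(pair_id = "p", condition = "c",
                      category = "normal")
    s1 <- summarizeDominance(rec)
    expect_identical(s1$total, 1L)
    expect_equal(s1$pct_normal, 100.00)
    # excluded records never enter the total
    rec2 <- rbind(rec, data.frame(pair_id = "q", condition = "c",
                                  category = "excluded"))
    expect_identical(summarizeDominance(rec2)$total, 1L)
    # percentages sum to 100 within rounding slack
    set.seed(3)
    rnd <- matrix(rpois(15, 500) + 1, nrow = 3)
    colnames(rnd) <- c("BSB-HES", "TC-HEB", "TC-HES", "BSB-HEB",
                       "normal")
    srnd <- summarizeDominance(rnd)
    pct_sum <- rowSums(srnd[, paste0("pct_", colnames(rnd))])
    expect_true(all(abs(pct_sum - 100) <= 0.05))
})

test_that("shared/specific partition matches a set-algebra oracle", {
    a <- data.frame(pair_id = paste0("p", 1:6),
                    category = c("BSB-HES", "TC-HEB", "TC-HES",
                                 "BSB-HEB", "normal", "BSB-HES"))
    # identical sets: all shared
    full <- sharedSpecificPartition(a, a)
    expect_true(all(full$specific == 0))
    expect_identical(full$shared, c(3L, 2L))
    # disjoint dominant sets: nothing shared
    b <- a; b$category <- c("normal", "normal", "normal", "normal",
                            "TC-HEB", "normal")
    dis <- sharedSpecificPartition(a, b)
    expect_identical(dis$shared, c(0L, 0L))
    # randomized toys vs an explicit set-intersection oracle
    set.seed(12)
    for (k in 1:5) {
        mk <- function() data.frame(
            pair_id = paste0("p", 1:30),
            category = sample(c("BSB-HES", "TC-HEB", "TC-HES",
                                "BSB-HEB", "normal", "excluded"),
                              30, replace = TRUE))
        x <- mk(); y <- mk()
        got <- sharedSpecificPartition(x, y)
        tc_x <- x$pair_id[x$category %in% c("BSB-HES", "TC-HEB")]
        tc_y <- y$pair_id[y$category %in% c("BSB-HES", "TC-HEB")]
        expect_identical(got$shared[1], length(intersect(tc_x, tc_y)))
        expect_identical(got$specific[1],
                         length(union(tc_x, tc_y)) -
                         length(intersect(tc_x, tc_y)))
    }
})

test_that("summary TSV twin files mirror the published table layout", {
    counts <- matrix(c(10, 5, 2, 3, 20), nrow = 1,
                     dimnames = list("G1",
                                     c("BSB-HES", "TC-HEB", "TC-HES",
                                       "BSB-HEB", "normal")))
    s <- summarizeDominance(counts)
    f1 <- tempfile(); f2 <- tempfile()
    writeDominanceSummary(s, f1, f2)
    cc <- utils::read.delim(f1, check.names = FALSE)
    expect_identical(names(cc),
                     c("condition", "BSB-HES", "TC-HEB", "TC-HES",
                       "BSB-HEB", "normal", "total"))
    expect_identical(cc$total, 40L)
    pp <- utils::read.delim(f2, check.names = FALSE)
    expect_match(pp$`BSB-HES`, "^10 \\(25\\.00%\\)$")
})
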