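test_that("KS statistic and p-value behave on canonical splits", {
    # identical samples: no separation
    same <- ksTwoSample(c(1, 2, 3), c(1, 2, 3))
    expect_equal(same$statistic, 0)
    expect_equal(same$p.value, 1)
    expect_true(same$tied)

    # complete separation of 2 vs 3: 2 of the 10 interleavings reach D=1
    sep <- ksTwoSample(c(4, 5), c(1, 2, 3))
    expect_equal(sep$statistic, 1)
    expect_equal(sep$p.value, 0.2, tolerance = 1e-15)
    expect_true(sep$exact)

    expect_error(ksTwoSample(numeric(), c(1, 2)), "degenerate")
    expect_error(ksTwoSample(c(1, NA), c(1, 2)), "finite")
})

test_that("exact KS p-values agree with stats::ks.test across sizes", {
    set.seed(19)
    for (cfg in list(c(3, 5), c(8, 7), c(30, 70), c(50, 250),
                     c(136, 164))) {
        x <- rnorm(cfg[1])
        y <- rnorm(cfg[2]) + 0.3
        mine <- ksTwoSample(x, y)
        ref <- suppressWarnings(stats::ks.test(x, y, exact = TRUE))
        expect_true(mine$exact)
        expect_equal(mine$statistic, unname(ref$statistic),
                     tolerance = 1e-12)
        expect_equal(mine$p.value, ref$p.value, tolerance = 1e-10)
    }
    # near-complete separation: tiny p must not underflow to zero
    x <- rnorm(50) + 5
    y <- rnorm(250)
    mine <- ksTwoSample(x, y)
    ref <- suppressWarnings(stats::ks.test(x, y, exact = TRUE))
    expect_gt(mine$p.value, 0)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-10)
})

test_that("tied pooled values fall back to the flagged asymptotic p", {
    res <- ksTwoSample(c(1, 2, 2, 5, 6), c(2, 3, 4, 7))
    expect_true(res$tied)
    expect_false(res$exact)
    ref <- suppressWarnings(stats::ks.test(c(1, 2, 2, 5, 6),
                                           c(2, 3, 4, 7),
                                           exact = FALSE))
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p.value, ref$p.value, tolerance = 1e-10)
})

test_that("BH adjustment matches the worked example and edge cases", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)),
                 rep(0.04, 4), tolerance = 1e-15)
    expect_equal(bhAdjust(0.37), 0.37)
    expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
    expect_error(bhAdjust(c(0.1, 0)), "\\(0, 1\\]")
    expect_error(bhAdjust(c(0.1, 1.2)), "\\(0, 1\\]")
})

test_that("enrichment on a ladder input reports the exact top-set p", {
    rt <- ladderRanked(10)
    db <- tinyDb(TaxonSet("top", paste0("t", 6:10),
                          category = "metabolite_producers"))
    res <- runTaxonSetEnrichment(rt, db, minSize = 5)
    expect_identical(nrow(res), 1L)
    expect_identical(res$set_id, "top")
    expect_identical(res$n_detected, 5L)
    expect_equal(res$median_rank, 8)
    # complete separation of 5 vs 5: 2 of the C(10,5)=252 interleavings
    expect_equal(res$p_value, 2 / 252, tolerance = 1e-12)
    expect_equal(res$fdr, res$p_value)
    expect_identical(res$detected_members, paste(paste0("t", 6:10),
                                                 collapse = ","))
    expect_false(res$tie_flag)
})

test_that("filtering, degenerate sets and empty results follow the contract", {
    rt <- ladderRanked(10)

    # nothing survives the default filter: empty table plus warning
    small <- tinyDb(TaxonSet("few", paste0("t", 1:3)))
    expect_warning(res <- runTaxonSetEnrichment(rt, small), "no taxon set")
    expect_identical(nrow(res), 0L)
    expect_named(res, c("set_id", "category", "n_detected",
                        "median_rank", "ks_statistic", "p_value",
                        "fdr", "detected_members", "tie_flag"))

    # a set spanning every input taxon has no background and is skipped
    db <- tinyDb(TaxonSet("all", paste0("t", 1:10)),
                 TaxonSet("top", paste0("t", 6:10)))
    expect_warning(res <- runTaxonSetEnrichment(rt, db), "every input taxon")
    expect_identical(res$set_id, "top")
    # BH ran over the single tested set only
    expect_equal(res$fdr, res$p_value)
})

test_that("results are invariant under taxon relabelling with values", {
    set.seed(23)
    vals <- rnorm(60, 0, 0.5)
    rt <- RankedTaxa(vals, taxa = sprintf("a%02d", 1:60))
    db <- TaxonSetDatabase(lapply(1:6, function(i)
        TaxonSet(paste0("s", i),
                 sprintf("a%02d", sample(1:60, sample(6:20, 1))))))
    res <- runTaxonSetEnrichment(rt, db)

    perm <- sample(60)
    rt2 <- RankedTaxa(vals[perm], taxa = sprintf("a%02d", (1:60)[perm]))
    res2 <- runTaxonSetEnrichment(rt2, db)
    # detected_members keeps set-declaration order, so compare stats
    expect_identical(res$set_id, res2$set_id)
    expect_identical(res[c("ks_statistic", "p_value", "fdr",
                           "median_rank")],
                     res2[c("ks_statistic", "p_value", "fdr",
                            "median_rank")])
})

test_that("result tables are sorted by fdr, then p, then set id", {
    set.seed(77)
    rt <- RankedTaxa(rnorm(80), taxa = paste0("t", 1:80))
    db <- TaxonSetDatabase(lapply(1:8, function(i)
        TaxonSet(paste0("s", i),
                 paste0("t", sample(1:80, sample(5:30, 1))))))
    res <- runTaxonSetEnrichment(rt, db)
    expect_false(is.unsorted(res$fdr))
    key <- order(res$fdr, res$p_value, res$set_id)
    expect_identical(key, seq_len(nrow(res)))
})
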