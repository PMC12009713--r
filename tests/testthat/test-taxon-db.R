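test_that("GMT parsing handles well-formed, duplicated and malformed input", {
    gmt <- withr::local_tempfile(fileext = ".gmt")

    writeLines("butyrate\tdesc\t853\t40518\t301301\t46503\t39491", gmt)
    db <- readTaxonSets(gmt)
    expect_length(db, 1L)
    expect_identical(members(db[["butyrate"]]),
                     c("853", "40518", "301301", "46503", "39491"))
    expect_identical(category(db[["butyrate"]]), "custom")

    writeLines("butyrate\tdesc\t853\t40518\t853\t46503\t39491", gmt)
    expect_warning(db2 <- readTaxonSets(gmt), "duplicate member")
    expect_length(members(db2[["butyrate"]]), 4L)

    writeLines(c("ok\tdesc\t853\t40518\t301301",
                 "broken\tonly-description"), gmt)
    expect_error(readTaxonSets(gmt), "line 2")

    writeLines(character(), gmt)
    expect_error(readTaxonSets(gmt), "no sets found")
})

test_that("JSON databases validate set ids and default the category", {
    js <- withr::local_tempfile(fileext = ".json")

    writeLines('[
      {"set_id": "a", "category": "metabolite_producers",
       "members": ["1", "2", "3"]},
      {"set_id": "b", "members": ["2", "4"]}
    ]', js)
    db <- readTaxonSets(js)
    expect_identical(category(db[["a"]]), "metabolite_producers")
    expect_identical(category(db[["b"]]), "custom")
    expect_identical(displayName(db[["b"]]), "b")

    writeLines('[
      {"set_id": "a", "members": ["1"]},
      {"set_id": "a", "members": ["2"]}
    ]', js)
    expect_error(readTaxonSets(js), "duplicate set ids")
})

test_that("databases round-trip through GMT and JSON", {
    db <- TaxonSetDatabase(list(
        TaxonSet("scfa", c("853", "301301", "39491"),
                 displayName = "SCFA producers"),
        TaxonSet("bloom", c("562", "573"),
                 displayName = "dysbiosis bloom")))
    asList <- function(d) lapply(taxonSets(d), function(s)
        list(setId(s), displayName(s), category(s), members(s)))

    for (fmt in c("gmt", "json")) {
        f <- withr::local_tempfile(fileext = paste0(".", fmt))
        writeTaxonSets(db, f, fmt)
        expect_identical(asList(readTaxonSets(f)), asList(db))
    }

    # JSON additionally preserves non-default categories
    db2 <- TaxonSetDatabase(list(
        TaxonSet("hd", c("1", "2"), category = "health_disease")))
    f <- withr::local_tempfile(fileext = ".json")
    writeTaxonSets(db2, f)
    expect_identical(category(readTaxonSets(f)[["hd"]]),
                     "health_disease")
})

test_that("detectability filtering obeys the minimum-size contract", {
    ranked <- ladderRanked(10)
    db <- tinyDb(
        TaxonSet("four", c("t1", "t2", "t3", "t4", "absent")),
        TaxonSet("five", paste0("t", 5:9)),
        TaxonSet("disjoint", c("x1", "x2", "x3", "x4", "x5")))

    f5 <- filterDetectable(db, ranked, minSize = 5)
    expect_identical(names(f5), "five")
    expect_identical(detectedMembers(f5)$five, paste0("t", 5:9))

    f4 <- filterDetectable(db, ranked, minSize = 4)
    expect_setequal(names(f4), c("four", "five"))
    expect_identical(detectedMembers(f4)$four, paste0("t", 1:4))

    # weakest filter keeps every set with at least one detected member
    f1 <- filterDetectable(db, ranked, minSize = 1)
    expect_setequal(names(f1), c("four", "five"))

    # no shared identifiers at all: legal empty database
    alien <- RankedTaxa(c(z1 = 0.1, z2 = -0.2))
    expect_length(filterDetectable(db, alien, minSize = 1), 0L)

    expect_error(filterDetectable(db, ranked, minSize = 0),
                 "positive integer")
})

test_that("detectability filtering is idempotent and monotone in minSize", {
    ranked <- ladderRanked(40)
    # sets drawn from a universe only partly covered by the input, so
    # detected counts vary across sets
    set.seed(31)
    db <- TaxonSetDatabase(lapply(1:7, function(i)
        TaxonSet(paste0("s", i),
                 sample(paste0("t", 1:55), sample(3:12, 1)))))
    prev <- Inf
    for (ms in c(1, 3, 5, 8)) {
        f <- filterDetectable(db, ranked, minSize = ms)
        expect_lte(length(f), prev)
        prev <- length(f)
        ff <- filterDetectable(f, ranked, minSize = ms)
        expect_identical(names(ff), names(f))
        expect_identical(detectedMembers(ff), detectedMembers(f))
    }
})

test_that("fixture databases are deterministic and respect class bounds", {
    db1 <- generateFixtureDB(5, 5, 5, universeSize = 300, seed = 1)
    db2 <- generateFixtureDB(5, 5, 5, universeSize = 300, seed = 1)
    f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
    writeTaxonSets(db1, f1, "json"); writeTaxonSets(db2, f2, "json")
    expect_identical(readLines(f1), readLines(f2))

    bounds <- list(small = c(2, 9), medium = c(10, 50),
                   large = c(51, 150))
    for (s in taxonSets(db1)) {
        cls <- sub("_.*", "", setId(s))
        expect_gte(length(s), bounds[[cls]][1])
        expect_lte(length(s), bounds[[cls]][2])
        expect_false(anyDuplicated(members(s)) > 0)
        expect_true(all(members(s) %in% fixtureUniverse(300)))
    }

    one <- generateFixtureDB(0, 1, 0, universeSize = 60, seed = 2)
    expect_length(one, 1L)
    expect_gte(length(one[[1]]), 10)
    expect_lte(length(one[[1]]), 50)

    expect_error(generateFixtureDB(1, 0, 0, universeSize = 1, seed = 3),
                 "cannot accommodate")
})
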