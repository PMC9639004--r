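test_that("xylan fixture has the expected topology", {
  s <- build_xylan_scheme()
  expect_length(s$species, 4)
  expect_setequal(names(s$species), c("1a", "1b", "1c", "1d"))
  expect_identical(s$rate_symbols, c("k1", "k2", "k-2", "k3"))
  expect_identical(validate_scheme(s), character(0))
  # diacetylated species loses either acetyl through parallel k1 channels
  k1_rx <- s$reactions[s$reactions$rate_symbol == "k1", ]
  expect_identical(sort(k1_rx$product), c("1b", "1c"))
  expect_true(all(k1_rx$reactant == "1a"))
  # no cross-unit migration in xylan (no primary acceptor)
  expect_false(any(s$reactions$kind == "migration_crossunit"))
})

test_that("glucan fixture has the expected topology", {
  g <- build_glucan_scheme()
  expect_length(g$species, 7)
  expect_identical(g$rate_symbols,
                   c("k1", "k2", "k-2", "k3", "k_hydr_prim", "k_hydr_sec"))
  expect_identical(validate_scheme(g), character(0))
  counts <- acetyl_counts(g)
  expect_identical(counts[["2a"]], 2L)
  expect_identical(counts[["2g"]], 0L)
  # cross-unit migrations are irreversible secondary -> primary
  cross <- g$reactions[g$reactions$kind == "migration_crossunit", ]
  expect_identical(cross$rate_symbol, c("k1", "k3"))
  expect_identical(cross$reactant, c("2a", "2e"))
  expect_true(all(cross$product %in% c("2b", "2f")))
  # migrations conserve the acetyl count, hydrolyses remove exactly one
  dn <- counts[g$reactions$reactant] - counts[g$reactions$product]
  is_mig <- grepl("^migration", g$reactions$kind)
  expect_true(all(dn[is_mig] == 0L))
  expect_true(all(dn[!is_mig] == 1L))
})

test_that("validate_scheme flags forced violations", {
  s <- build_xylan_scheme()
  # a migration that changes the acetyl count
  bad <- s
  bad$reactions$kind[bad$reactions$rate_symbol == "k3"][1] <-
    "migration_adjacent"
  v <- validate_scheme(bad)
  expect_length(v, 1)
  expect_match(v, "migration changes acetyl count")

  # an orphan rate symbol
  orphan <- s
  orphan$rate_symbols <- c(orphan$rate_symbols, "k_unused")
  v <- validate_scheme(orphan)
  expect_length(v, 1)
  expect_match(v, "never used")

  # self-loop and unknown species
  loop <- s
  loop$reactions$product[1] <- loop$reactions$reactant[1]
  expect_match(validate_scheme(loop), "reactant equals product", all = FALSE)

  # stranded acetylated species: cut both hydrolysis channels out of 1b/1c
  stranded <- s
  stranded$reactions <- stranded$reactions[stranded$reactions$rate_symbol
                                           != "k3", ]
  stranded$rate_symbols <- setdiff(stranded$rate_symbols, "k3")
  expect_match(validate_scheme(stranded), "path to full deacetylation",
               all = FALSE)
})

test_that("total acetyl content is non-increasing under the dynamics", {
  # d/dt sum_i n_i y_i = n' A y must be <= 0 for any state: migration
  # moves acetyls between species, only hydrolysis removes them
  set.seed(42)
  for (s in list(build_xylan_scheme(), build_glucan_scheme())) {
    n <- acetyl_counts(s)
    for (rep in 1:5) {
      A <- rate_matrix(s, random_rates(s))
      y <- runif(length(n)); y <- y / sum(y)
      expect_lte(as.numeric(t(n) %*% A %*% y), 1e-12)
    }
  }
})

test_that("fixture schemes round-trip through the JSON format", {
  for (s in list(build_xylan_scheme(), build_glucan_scheme())) {
    f1 <- withr::local_tempfile(fileext = ".json")
    f2 <- withr::local_tempfile(fileext = ".json")
    write_scheme(s, f1)
    s2 <- read_scheme(f1)
    expect_identical(s2$name, s$name)
    expect_identical(s2$species, s$species)
    expect_identical(s2$rate_symbols, s$rate_symbols)
    expect_identical(validate_scheme(s2), character(0))
    # byte-identical after one normalising round trip
    write_scheme(s2, f2)
    expect_identical(readLines(f1), readLines(f2))
  }
})

test_that("unknown scheme names are rejected with the fixture list", {
  expect_error(get_scheme("mannan"), "xylan, glucan")
  expect_identical(get_scheme("xylan")$name, "xylan")
})
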