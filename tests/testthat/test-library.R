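glu_libs <- function() published_libraries("glucuronide")
gal_libs <- function() published_libraries("galactoside")

test_that("published library fixtures parse with their table anchors", {
  glu <- glu_libs()
  expect_length(glu, 3)
  for (l in glu) expect_equal(nrow(l$mutants), 10)
  expect_equal(glu$km$wildtype_energy, -489.4)
  expect_equal(glu$km$wildtype, "HDFVGLGWN")
  expect_equal(glu$km$mutants$energy[1], -1548.7)
  expect_equal(glu$km$mutants$sequence[1], "QDQAAGDRG")
  gal <- gal_libs()
  expect_equal(gal$efficiency$wildtype_energy, 90.1)
  expect_equal(gal$kcat$wildtype_energy, 25.4)
})

test_that("library tables round-trip bit-exactly through the writer", {
  for (l in c(glu_libs(), gal_libs())) {
    f <- tempfile(fileext = ".tsv")
    write_design_library(l, f)
    back <- read_design_library(f)
    expect_equal(back$mutants, l$mutants)
    expect_identical(back$wildtype, l$wildtype)
    expect_identical(back$positions, l$positions)
    expect_equal(back$wildtype_energy, l$wildtype_energy)
    # writing again is byte-identical
    f2 <- tempfile(fileext = ".tsv")
    write_design_library(back, f2)
    expect_identical(readLines(f), readLines(f2))
  }
  f <- tempfile()
  writeLines(c("# name: x", "# objective: KM", "rank\tenergy\t1\t2",
               "WT\t0\tA\tB", "1\t-5\tA"), f)
  expect_error(read_design_library(f), "malformed library row")
})

test_that("pooled frequencies reproduce the serine-162 contrast", {
  ft_glu <- frequency_table(unname(glu_libs()))
  expect_equal(attr(ft_glu, "n_mutants"), 30)
  s_glu <- ft_glu$freq[ft_glu$position == 162 & ft_glu$aa == "S"]
  expect_equal(s_glu, 4 / 30)                       # 13.3%
  ft_gal <- frequency_table(unname(gal_libs()))
  s_gal <- ft_gal$freq[ft_gal$position == 162 & ft_gal$aa == "S"]
  expect_equal(s_gal, 11 / 30)                      # 36.7%
  # per position, frequencies sum to one
  sums <- tapply(ft_glu$freq, ft_glu$position, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # a single-mutant library is 100% everywhere
  solo <- design_library("solo", "KM", c(1, 2),
                         tibble::tibble(rank = 1, energy = -1,
                                        sequence = "AK"), "GG")
  ft1 <- frequency_table(solo)
  expect_true(all(ft1$freq == 1))
})

test_that("representative mutations follow the 15%/10-point rule", {
  mk <- function(name, seqs)
    design_library(name, "KM", c(1, 2),
                   tibble::tibble(rank = seq_along(seqs), energy = -1,
                                  sequence = seqs), "GG")
  target <- mk("t", c("AK", "AK", "AK", "GG", "GG", "GG", "GG", "GG", "GG",
                      "GG"))                      # A@1 = 0.3, K@2 = 0.3
  other <- mk("o", c("AK", "GG", "GG", "GG", "GG", "GG", "GG", "GG", "GG",
                     "GG"))                       # A@1 = 0.1
  rep1 <- representative_mutations(target, list(other))
  expect_true(any(rep1$position == 1 & rep1$aa == "A"))   # 0.3 vs 0.1
  # margin below 10 points is excluded (A@1 = 0.25 in the comparison)
  other2 <- mk("o2", c(rep("AG", 5), rep("GG", 15)))
  rep2 <- representative_mutations(target, list(other2))
  expect_false(any(rep2$position == 1 & rep2$aa == "A")) # 0.3 - 0.25 < 0.10
  # a margin of exactly 10 points is inclusive
  rep2b <- representative_mutations(
    target, list(mk("o2b", c(rep("AG", 2), rep("GG", 8)))))
  expect_true(any(rep2b$position == 1 & rep2b$aa == "A")) # 0.3 - 0.2 = 0.10
  # wild-type residues are never reported
  expect_false(any(rep1$aa == "G"))
  # inclusive thresholds: exactly 15% and exactly 10 points qualify
  t3 <- mk("t3", c("AG", "AG", "AG", rep("GG", 17)))      # A@1 = 0.15
  o3 <- mk("o3", c("AG", rep("GG", 19)))                  # A@1 = 0.05
  rep3 <- representative_mutations(t3, list(o3))
  expect_true(any(rep3$position == 1 & rep3$aa == "A"))
})

test_that("W549R is representative of the galactoside efficiency library", {
  gal <- gal_libs()
  rep <- representative_mutations(gal$efficiency, list(gal$km, gal$kcat))
  hit <- rep[rep$position == 549 & rep$aa == "R", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$freq, 0.6)
  expect_equal(hit$freq_others, 0.2)
})

test_that("representative mutations are order-invariant and shrink monotonically", {
  gal <- gal_libs()
  shuffled <- gal$efficiency
  set.seed(4)
  shuffled$mutants <- shuffled$mutants[sample(nrow(shuffled$mutants)), ]
  r1 <- representative_mutations(gal$efficiency, list(gal$km, gal$kcat))
  r2 <- representative_mutations(shuffled, list(gal$km, gal$kcat))
  expect_equal(dplyr::arrange(r1, position, aa),
               dplyr::arrange(r2, position, aa))
  # raising either threshold never enlarges the set
  for (mf in c(0.15, 0.3, 0.5)) for (mg in c(0.1, 0.2, 0.4)) {
    sub <- representative_mutations(gal$efficiency, list(gal$km, gal$kcat),
                                    min_frequency = mf, margin = mg)
    expect_true(all(paste(sub$position, sub$aa) %in%
                      paste(r1$position, r1$aa)))
  }
})

test_that("representative and enrichment rules match an exhaustive scan", {
  glu <- glu_libs(); gal <- gal_libs()
  freqs <- function(lib) {
    ft <- frequency_table(lib)
    function(p, a) {
      v <- ft$freq[ft$position == p & ft$aa == a]
      if (length(v)) v else 0
    }
  }
  # representative rule, every library as target in turn
  all_aa <- c("A","R","N","D","C","Q","E","G","H","I",
              "L","K","M","F","P","S","T","W","Y","V")
  wt <- stats::setNames(strsplit(glu$km$wildtype, "")[[1]],
                        glu$km$positions)
  for (tgt in names(gal)) {
    others <- gal[setdiff(names(gal), tgt)]
    got <- representative_mutations(gal[[tgt]], unname(others))
    ftt <- freqs(gal[[tgt]]); fto <- lapply(unname(others), freqs)
    manual <- list()
    for (p in gal[[tgt]]$positions) for (a in all_aa) {
      if (a == wt[[as.character(p)]]) next
      f <- ftt(p, a)
      fo <- max(vapply(fto, function(fn) fn(p, a), 0))
      if (f >= 0.15 - 1e-9 && f - fo >= 0.10 - 1e-9)
        manual[[length(manual) + 1]] <- paste(p, a)
    }
    expect_setequal(paste(got$position, got$aa), unlist(manual))
  }
  # enrichment rule with the default thresholds
  got <- enriched_in_group_absent_in_group(unname(gal), unname(glu))
  fa <- lapply(unname(gal), freqs); fb <- lapply(unname(glu), freqs)
  manual <- list()
  for (p in glu$km$positions) for (a in all_aa) {
    if (a == wt[[as.character(p)]]) next
    va <- vapply(fa, function(fn) fn(p, a), 0)
    vb <- vapply(fb, function(fn) fn(p, a), 0)
    if (all(va >= 0.10 - 1e-9) && all(vb <= 0.05 + 1e-9))
      manual[[length(manual) + 1]] <- paste(p, a)
  }
  expect_setequal(paste(got$position, got$aa), unlist(manual))
})

test_that("group enrichment obeys its two thresholds on toy libraries", {
  mk <- function(name, seqs)
    design_library(name, "KM", 1L,
                   tibble::tibble(rank = seq_along(seqs), energy = -1,
                                  sequence = seqs), "G")
  a1 <- mk("a1", c("R", "R", "G", "G")); a2 <- mk("a2", c("R", "R", "R", "G"))
  b1 <- mk("b1", c("G", "G", "G", "G")); b2 <- mk("b2", c("R", "R", "G", "G"))
  # present in all of A (0.5, 0.75), absent from all of B (0, 0)
  got <- enriched_in_group_absent_in_group(list(a1, a2), list(b1))
  expect_true(any(got$position == 1 & got$aa == "R"))
  # present in one of B at 0.5 -> excluded
  got2 <- enriched_in_group_absent_in_group(list(a1, a2), list(b1, b2))
  expect_false(any(got2$position == 1 & got2$aa == "R"))
})

test_that("frequency tables plot and error on empty input", {
  ft <- frequency_table(unname(glu_libs()))
  expect_s3_class(autoplot(ft), "ggplot")
  empty <- design_library("e", "KM", 1L,
                          tibble::tibble(rank = integer(0),
                                         energy = numeric(0),
                                         sequence = character(0)), "G")
  expect_error(frequency_table(empty), "empty")
})
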