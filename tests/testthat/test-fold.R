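test_that("fold_mfe recovers known structures and energies", {
  em <- energy_model()
  expect_equal(fold_mfe("AAAAAA", em)$energy, 0)
  expect_equal(nrow(fold_mfe("AAAAAA", em)$pairs), 0)

  hp <- fold_mfe("GGGAAAACCC", em)
  # three stacked GC pairs closing a 4-nt loop
  expect_equal(nrow(hp$pairs), 3)
  expect_equal(hp$energy, 3 * (-3) + 2 * (-0.5))
  expect_equal(hp$dot_bracket, "(((....)))")

  expect_error(fold_mfe("GGXACC"), "invalid RNA")
  expect_error(fold_mfe(""), "non-empty")
})

test_that("duplex_energy matches the model's closed forms", {
  em <- energy_model()
  # perfect all-GC duplex: init + 4 pairs + 3 stacks
  d <- duplex_energy("GGGG", "CCCC", em)
  expect_equal(d$energy, 2 + 4 * (-3) + 3 * (-0.5))
  expect_equal(nrow(d$pairs), 4)
  # nothing pairs
  expect_equal(duplex_energy("AAAA", "AAAA", em)$energy, 0)
  expect_equal(nrow(duplex_energy("AAAA", "AAAA", em)$pairs), 0)
  # mixed perfect complement of length L
  s <- "GAUCCGUA"
  d2 <- duplex_energy(s, rna_revcomp(s), em)
  per_pair <- sum(vapply(strsplit(s, "")[[1]], function(x) {
    if (x %in% c("G", "C")) -3 else -2
  }, numeric(1)))
  expect_equal(d2$energy, 2 + per_pair + 7 * (-0.5))
  expect_error(duplex_energy("", "ACGU"), "non-empty")
})

test_that("appending complementary bases never raises duplex energy", {
  em <- energy_model()
  withr::with_seed(101, {
    for (rep in 1:20) {
      core <- random_rna_str(sample(4:10, 1))
      prev <- duplex_energy(core, rna_revcomp(core), em)$energy
      ext <- core
      for (k in 1:5) {
        ext <- paste0(ext, sample(c("A", "C", "G", "U"), 1))
        cur <- duplex_energy(ext, rna_revcomp(ext), em)$energy
        expect_lte(cur, prev)
        prev <- cur
      }
    }
  })
})

test_that("returned structures are nested and respect the minimum loop", {
  em <- energy_model()
  withr::with_seed(77, {
    for (rep in 1:50) {
      s <- random_rna_str(sample(5:40, 1))
      p <- fold_mfe(s, em)$pairs
      if (nrow(p) == 0) next
      expect_true(all(p[, 2] - p[, 1] > em$min_loop))
      expect_equal(anyDuplicated(c(p[, 1], p[, 2])), 0)
      # nesting: no crossing pairs
      if (nrow(p) > 1) {
        for (x in seq_len(nrow(p) - 1)) {
          for (y in seq.int(x + 1, nrow(p))) {
            i <- p[x, 1]; j <- p[x, 2]; k <- p[y, 1]; l <- p[y, 2]
            crossing <- (i < k & k < j & j < l) | (k < i & i < l & l < j)
            expect_false(crossing)
          }
        }
      }
    }
  })
})

test_that("defect_score is a normalized base-pair distance", {
  em <- energy_model()
  s <- "GGGAAAACCC"
  mfe <- fold_mfe(s, em)
  expect_equal(defect_score(s, mfe, em), 0)
  # fully unpaired target on a strong hairpin: defect = paired fraction
  empty_target <- matrix(integer(0), 0, 2)
  expect_equal(defect_score(s, empty_target, em),
               2 * nrow(mfe$pairs) / nchar(s))
  withr::with_seed(5, {
    for (rep in 1:20) {
      a <- random_rna_str(12)
      b <- random_rna_str(12)
      d <- defect_score(a, fold_mfe(b, em), em)
      expect_gte(d, 0)
      expect_lte(d, 1)
    }
  })
  expect_error(defect_score("ACGU", matrix(c(0L, 9L), 1, 2), em),
               "out of range")
})

test_that("accessibility counts unpaired bases in a region", {
  em <- energy_model()
  # poly-A overhang on a core with no A-partners stays fully accessible
  s <- paste0("GGGGGGCCCCCC", "AAAAAA")
  expect_equal(accessibility(s, c(12, 18), em), 1.0)
  # overhang fully complementary to the core is fully paired
  s2 <- paste0("GGGGGG", "AAAA", "CCCCCC")
  expect_equal(accessibility(s2, c(10, 16), em), 0.0)
  # whole-sequence region equals 1 - paired fraction
  withr::with_seed(9, {
    s3 <- random_rna_str(30)
    f <- fold_mfe(s3, em)
    expect_equal(accessibility(s3, c(0, 30), em),
                 1 - 2 * nrow(f$pairs) / 30)
  })
  expect_error(accessibility("ACGU", c(2, 2), em), "empty region")
})

test_that("crosstalk_matrix flags strong non-cognate interactions only", {
  em <- energy_model()
  a <- c(x = "GGGGGGGGGG")
  expect_equal(dim(crosstalk_matrix(a, a, em)$energy), c(1, 1))
  tr <- c(t1 = "GGGGGGGGGGGG", t2 = "AAAAAAAAAAAA")
  sw <- c(s1 = "CCCCCCCCCCCC", s2 = "GGGGGGGGGGGG")
  ct <- crosstalk_matrix(tr, sw, em, threshold = -20)
  # cognate diagonal exempt even though strongly bound
  expect_false(ct$flag[1, 1])
  # t1 binds nothing off-diagonal strongly; t2 is inert
  expect_false(any(ct$flag[2, ]))
  # a trigger is the strongest entry in its cognate switch's column
  expect_true(ct$energy[1, 1] < ct$energy[2, 1])
})

test_that("long duplex runs are detected and broken by bulges", {
  em <- energy_model()
  s <- random_rna_str_fixed <- "GAUCCGUAAGCUGGAUCCGUAAGCUGGAUC"  # 30 nt
  full <- rna_revcomp(s)
  runs <- long_duplex_check(s, full, em, max_stem = 20)
  expect_length(runs, 1)
  expect_equal(runs[[1]][3], 30)
  # single-nt bulge in the middle splits the run: both halves pass
  bulged <- paste0(substr(full, 1, 15), "A", substr(full, 16, 30))
  expect_length(long_duplex_check(s, bulged, em, max_stem = 20), 0)
  # short complement passes
  expect_length(long_duplex_check("GGGGGGGGGG", "CCCCCCCCCC", em), 0)
})

test_that("hairpin presence agrees with an external folding engine", {
  # ViennaRNA RNAfold as an independent thermodynamic engine: we only
  # compare hairpin presence/absence on clear-cut sequences, not
  # energies (the internal model uses its own units)
  rnafold <- Sys.which("RNAfold")
  expect_true(nzchar(rnafold))
  run_fold <- function(seq) {
    out <- system2(rnafold, args = "--noPS", input = seq, stdout = TRUE)
    db <- strsplit(out[2], " ")[[1]][1]
    grepl("\\(", db)
  }
  sw <- toy_switch()
  strong <- switch_sequence(sw)
  expect_true(run_fold(strong))
  expect_true(nrow(fold_mfe(strong)$pairs) > 0)
  inert <- "AAACAACAAACAACAAACAA"
  expect_false(run_fold(inert))
  expect_equal(nrow(fold_mfe(inert)$pairs), 0)
})
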