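# Independent brute-force oracles for the folding and duplex engines,
# plus closed forms used to check the equilibrium solver.  These
# enumerate structures exhaustively and share nothing with the DP
# implementations.

oracle_pair_energy <- function(x, y, model) {
  key <- paste0(x, y)
  pe <- model$pair_energy
  if (key %in% c("GC", "CG")) pe[["GC"]]
  else if (key %in% c("AU", "UA")) pe[["AU"]]
  else if (key %in% c("GU", "UG")) pe[["GU"]]
  else 0
}

# all nested structures of seq (1-based pair lists), min_loop enforced
oracle_enum_structures <- function(chars, model) {
  n <- length(chars)
  min_loop <- model$min_loop
  rec <- function(i, j) {
    if (i >= j) return(list(matrix(0L, 0, 2)))
    res <- rec(i + 1, j)
    ks <- seq.int(i + min_loop + 1, j)
    ks <- ks[ks <= j & ks > i + min_loop]
    for (k in ks) {
      if (oracle_pair_energy(chars[i], chars[k], model) == 0) next
      inner <- rec(i + 1, k - 1)
      outer <- rec(k + 1, j)
      for (x in inner) {
        for (y in outer) {
          res[[length(res) + 1]] <- rbind(c(i, k), x, y)
        }
      }
    }
    res
  }
  rec(1L, n)
}

oracle_score_fold <- function(pairs, chars, model) {
  if (nrow(pairs) == 0) return(0)
  e <- 0
  key <- paste(pairs[, 1], pairs[, 2])
  for (r in seq_len(nrow(pairs))) {
    e <- e + oracle_pair_energy(chars[pairs[r, 1]], chars[pairs[r, 2]],
                                model)
    if (paste(pairs[r, 1] + 1, pairs[r, 2] - 1) %in% key) {
      e <- e + model$stack_bonus
    }
  }
  e
}

# exhaustive MFE by enumeration; returns minimum energy
oracle_fold_mfe <- function(seq, model) {
  chars <- strsplit(seq, "")[[1]]
  structs <- oracle_enum_structures(chars, model)
  min(vapply(structs, oracle_score_fold, numeric(1), chars = chars,
             model = model))
}

# all antiparallel intermolecular matchings of strands a and b
oracle_enum_matchings <- function(ca, cb, model) {
  n <- length(ca)
  m <- length(cb)
  rec <- function(i0, j1) {
    res <- list(matrix(0L, 0, 2))
    if (i0 > n || j1 < 1) return(res)
    for (i in i0:n) {
      for (j in seq_len(j1)) {
        if (oracle_pair_energy(ca[i], cb[j], model) == 0) next
        for (rest in rec(i + 1, j - 1)) {
          res[[length(res) + 1]] <- rbind(c(i, j), rest)
        }
      }
    }
    res
  }
  rec(1L, m)
}

oracle_score_duplex <- function(pairs, ca, cb, model) {
  if (nrow(pairs) == 0) return(0)
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  e <- model$duplex_init
  for (r in seq_len(nrow(pairs))) {
    e <- e + oracle_pair_energy(ca[pairs[r, 1]], cb[pairs[r, 2]], model)
    if (r > 1) {
      gap_a <- pairs[r, 1] - pairs[r - 1, 1] - 1
      gap_b <- pairs[r - 1, 2] - pairs[r, 2] - 1
      if (gap_a == 0 && gap_b == 0) {
        e <- e + model$stack_bonus
      } else {
        e <- e + model$bulge_penalty * (gap_a + gap_b)
      }
    }
  }
  e
}

# exhaustive best duplex energy (0 if nothing beats the empty duplex)
oracle_duplex_energy <- function(a, b, model) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  matchings <- oracle_enum_matchings(ca, cb, model)
  min(0, vapply(matchings, oracle_score_duplex, numeric(1), ca = ca,
                cb = cb, model = model))
}

# closed-form bound complex of S + T <-> C with association constant K
oracle_two_species <- function(S, T, K) {
  b <- S + T + 1 / K
  (b - sqrt(b^2 - 4 * S * T)) / 2
}

random_rna_str <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
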