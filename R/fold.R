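#' Predict the minimum-energy secondary structure of an RNA
#'
#' Nussinov-style dynamic programming over nested structures, extended
#' with a stacking bonus for directly adjacent pairs.  Used throughout
#' the design pipeline to screen switches, overhangs and cassettes.
#'
#' @param seq RNA string, 5'->3'.
#' @param model an [energy_model()].
#' @return A list with class \code{rna_structure}:
#'   \item{pairs}{two-column integer matrix of 0-based (i, j) pairs, i < j}
#'   \item{energy}{structure energy in model units (0 for no pairing)}
#'   \item{dot_bracket}{dot-bracket rendering}
#'   \item{n}{sequence length}
#' @examples
#' fold_mfe("GGGAAAACCC")
#' @export
fold_mfe <- function(seq, model = energy_model()) {
  if (nchar(seq) == 0) stop("sequence must be non-empty", call. = FALSE)
  enc <- encode_rna(seq)
  res <- .fold_mfe_cpp(enc, pair_matrix(model), model$stack_bonus,
                       model$min_loop)
  pairs <- res$pairs
  energy <- res$energy
  if (nrow(pairs) == 0) energy <- 0
  if (nrow(pairs) > 1) pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  structure(
    list(pairs = pairs, energy = energy,
         dot_bracket = dot_bracket(pairs, length(enc)), n = length(enc)),
    class = "rna_structure"
  )
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(x$dot_bracket, "\n")
  cat(sprintf("%d pairs, energy %g units\n", nrow(x$pairs), x$energy))
  invisible(x)
}

# render a pair list as dot-bracket notation (0-based pairs)
dot_bracket <- function(pairs, n) {
  db <- rep(".", n)
  if (nrow(pairs) > 0) {
    db[pairs[, 1] + 1] <- "("
    db[pairs[, 2] + 1] <- ")"
  }
  paste(db, collapse = "")
}

#' Best intermolecular duplex between two RNA strands
#'
#' Finds the optimal antiparallel intermolecular pairing of two strands
#' (no intramolecular pairs), scoring base pairs, stacking, a per-
#' interruption bulge penalty and duplex initiation.  A candidate duplex
#' whose total energy is non-negative is reported as no interaction.
#'
#' @param a,b RNA strings, 5'->3'.
#' @param model an [energy_model()].
#' @return A list with class \code{rna_duplex}:
#'   \item{pairs}{two-column matrix of 0-based (i in a, j in b) pairs,
#'     ascending in i (descending in j: strands are antiparallel)}
#'   \item{energy}{duplex energy in model units (0 when no duplex forms)}
#' @examples
#' duplex_energy("GGGG", "CCCC")$energy  # 2 + 4*(-3) + 3*(-0.5) = -11.5
#' @export
duplex_energy <- function(a, b, model = energy_model()) {
  if (nchar(a) == 0 || nchar(b) == 0) {
    stop("both sequences must be non-empty", call. = FALSE)
  }
  ea <- encode_rna(a)
  eb <- encode_rna(b)
  res <- .duplex_cpp(ea, eb, pair_matrix(model), model$stack_bonus,
                     model$bulge_penalty, model$duplex_init)
  structure(list(pairs = res$pairs, energy = res$energy,
                 n_a = length(ea), n_b = length(eb)),
            class = "rna_duplex")
}

#' @export
print.rna_duplex <- function(x, ...) {
  cat(sprintf("RNA duplex: %d pairs, energy %g units\n",
              nrow(x$pairs), x$energy))
  invisible(x)
}

#' Structure-defect score against a target structure
#'
#' Normalised base-pair distance between the predicted MFE structure of
#' \code{seq} and a target structure: the fraction of positions whose
#' pairing status (partner or unpaired) differs.  A cheap stand-in for a
#' full ensemble-defect computation, used to rank design candidates.
#'
#' @param seq RNA string.
#' @param target either an \code{rna_structure} or a two-column 0-based
#'   pair matrix giving the intended structure.
#' @param model an [energy_model()].
#' @return Defect fraction in \[0, 1\]; 0 when predicted equals target.
#' @export
defect_score <- function(seq, target, model = energy_model()) {
  n <- nchar(seq)
  tp <- if (inherits(target, "rna_structure")) target$pairs else target
  tp <- as.matrix(tp)
  if (nrow(tp) > 0 && (max(tp) >= n || min(tp) < 0)) {
    stop("target pair indices out of range", call. = FALSE)
  }
  mfe <- fold_mfe(seq, model)
  partner_of <- function(pairs, n) {
    p <- rep(NA_integer_, n)
    if (nrow(pairs) > 0) {
      p[pairs[, 1] + 1] <- pairs[, 2]
      p[pairs[, 2] + 1] <- pairs[, 1]
    }
    p
  }
  pa <- partner_of(mfe$pairs, n)
  pb <- partner_of(tp, n)
  differs <- xor(is.na(pa), is.na(pb)) |
    (!is.na(pa) & !is.na(pb) & pa != pb)
  sum(differs) / n
}

#' Fraction of a region left unpaired in the predicted MFE structure
#'
#' @param seq RNA string.
#' @param region integer vector \code{c(start, end)} of 0-based,
#'   half-open coordinates into \code{seq}.
#' @param model an [energy_model()].
#' @return Fraction of bases in the region that are unpaired.
#' @export
accessibility <- function(seq, region, model = energy_model()) {
  n <- nchar(seq)
  start <- region[1]
  end <- region[2]
  if (end <= start) stop("empty region", call. = FALSE)
  if (start < 0 || end > n) stop("region out of range", call. = FALSE)
  mfe <- fold_mfe(seq, model)
  paired <- unique(c(mfe$pairs[, 1], mfe$pairs[, 2]))
  idx <- seq.int(start, end - 1)
  sum(!(idx %in% paired)) / length(idx)
}

#' Pairwise duplex-energy crosstalk matrix
#'
#' Computes the duplex energy of every pair of species across two lists
#' and flags non-cognate pairs whose interaction is stronger than a
#' threshold.  Cognate pairs (same index, or declared via
#' \code{cognate}) are exempt from flagging.
#'
#' @param species_a,species_b named character vectors of RNA sequences.
#' @param model an [energy_model()].
#' @param threshold energy threshold in model units; a non-cognate pair
#'   with duplex energy below (stronger than) this value is flagged.
#' @param cognate optional two-column matrix of (row, column) indices of
#'   cognate pairs; defaults to the diagonal.
#' @return A list with \code{energy} (matrix), \code{flag} (logical
#'   matrix) and \code{threshold}.
#' @export
crosstalk_matrix <- function(species_a, species_b, model = energy_model(),
                             threshold = -6, cognate = NULL) {
  if (length(species_a) == 0 || length(species_b) == 0) {
    stop("species lists must be non-empty", call. = FALSE)
  }
  na <- length(species_a)
  nb <- length(species_b)
  e <- matrix(0, na, nb,
              dimnames = list(names(species_a), names(species_b)))
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      e[i, j] <- duplex_energy(species_a[[i]], species_b[[j]], model)$energy
    }
  }
  is_cognate <- matrix(FALSE, na, nb)
  if (is.null(cognate)) {
    d <- seq_len(min(na, nb))
    is_cognate[cbind(d, d)] <- TRUE
  } else if (nrow(cognate) > 0) {
    is_cognate[as.matrix(cognate)] <- TRUE
  }
  flag <- (e < threshold) & !is_cognate
  list(energy = e, flag = flag, threshold = threshold)
}

#' Detect long uninterrupted double-stranded runs in a duplex
#'
#' Long perfect RNA duplexes are substrates for double-strand-specific
#' ribonucleases; designs avoid them by interrupting pairing with
#' single-nucleotide bulges.  This check reports every contiguous run of
#' intermolecular pairs longer than \code{max_stem} in the best duplex.
#'
#' @param a,b RNA strings.
#' @param model an [energy_model()].
#' @param max_stem maximum tolerated contiguous duplex length (bp).
#' @return A list of runs, each \code{c(start_a, end_a, length)} with
#'   0-based half-open coordinates on \code{a}; empty list means pass.
#' @export
long_duplex_check <- function(a, b, model = energy_model(), max_stem = 20) {
  dx <- duplex_energy(a, b, model)
  runs <- duplex_runs(dx$pairs)
  runs[vapply(runs, function(r) r[3] > max_stem, logical(1))]
}

# split a duplex pair list (ascending i, descending j) into contiguous
# helical runs; returns list of c(start_a, end_a_exclusive, length)
duplex_runs <- function(pairs) {
  if (nrow(pairs) == 0) return(list())
  runs <- list()
  start <- 1
  for (r in seq_len(nrow(pairs))[-1]) {
    contig <- pairs[r, 1] == pairs[r - 1, 1] + 1 &&
      pairs[r, 2] == pairs[r - 1, 2] - 1
    if (!contig) {
      runs[[length(runs) + 1]] <-
        c(pairs[start, 1], pairs[r - 1, 1] + 1, r - start)
      start <- r
    }
  }
  runs[[length(runs) + 1]] <-
    c(pairs[start, 1], pairs[nrow(pairs), 1] + 1, nrow(pairs) - start + 1)
  runs
}
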