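#' Nucleotide-level RNA energy model
#'
#' A coarse-grained energy model for the internal folding and duplex
#' engine.  Energies are in dimensionless "units", not kcal/mol: the model
#' is a rank-ordering device for screening candidate designs, not a
#' thermodynamic predictor.  Watson-Crick and wobble pairs contribute
#' negative (favourable) energies, adjacent pairs earn a stacking bonus,
#' bulges and duplex initiation are penalised.
#'
#' @param pair_energy named numeric vector with elements \code{GC},
#'   \code{AU} and \code{GU}: energy per base pair (must be negative).
#' @param stack_bonus energy added for every pair stacked directly on
#'   another pair (must be <= 0).
#' @param bulge_penalty energy added per nucleotide looped out of a
#'   duplex interruption (a single-nucleotide bulge costs one penalty;
#'   larger bulges and internal loops cost proportionally more), >= 0.
#' @param min_loop minimum number of unpaired bases enclosed by a hairpin
#'   loop, >= 3.
#' @param duplex_init initiation penalty for forming an intermolecular
#'   duplex, >= 0.
#'
#' @return An object of class \code{energy_model}.
#' @examples
#' em <- energy_model()
#' em$pair_energy[["GC"]]
#' @export
energy_model <- function(pair_energy = c(GC = -3, AU = -2, GU = -1),
                         stack_bonus = -0.5,
                         bulge_penalty = 3,
                         min_loop = 3,
                         duplex_init = 2) {
  stopifnot(all(c("GC", "AU", "GU") %in% names(pair_energy)))
  if (any(pair_energy >= 0)) {
    stop("pairing energies must be negative", call. = FALSE)
  }
  if (stack_bonus > 0) stop("stack_bonus must be <= 0", call. = FALSE)
  if (bulge_penalty < 0) stop("bulge_penalty must be >= 0", call. = FALSE)
  if (min_loop < 3) stop("min_loop must be >= 3", call. = FALSE)
  if (duplex_init < 0) stop("duplex_init must be >= 0", call. = FALSE)
  structure(
    list(pair_energy = pair_energy, stack_bonus = stack_bonus,
         bulge_penalty = bulge_penalty, min_loop = as.integer(min_loop),
         duplex_init = duplex_init),
    class = "energy_model"
  )
}

#' @export
print.energy_model <- function(x, ...) {
  cat("RNA energy model (arbitrary units)\n")
  cat(sprintf("  pair energies: GC=%g AU=%g GU=%g\n",
              x$pair_energy[["GC"]], x$pair_energy[["AU"]],
              x$pair_energy[["GU"]]))
  cat(sprintf("  stack %g, bulge +%g, duplex init +%g, min loop %d\n",
              x$stack_bonus, x$bulge_penalty, x$duplex_init, x$min_loop))
  invisible(x)
}

# 4x4 pair-energy lookup over encoded bases (A=0, C=1, G=2, U=3);
# zero marks a non-pairing combination.
pair_matrix <- function(model) {
  m <- matrix(0, 4, 4)
  gc <- model$pair_energy[["GC"]]
  au <- model$pair_energy[["AU"]]
  gu <- model$pair_energy[["GU"]]
  m[2 + 1, 1 + 1] <- gc; m[1 + 1, 2 + 1] <- gc  # G:C, C:G
  m[0 + 1, 3 + 1] <- au; m[3 + 1, 0 + 1] <- au  # A:U, U:A
  m[2 + 1, 3 + 1] <- gu; m[3 + 1, 2 + 1] <- gu  # G:U, U:G
  m
}

RNA_BASES <- c("A", "C", "G", "U")

# encode an RNA string to integers 0..3; errors on other characters
encode_rna <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  idx <- match(chars, RNA_BASES)
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    stop(sprintf("invalid RNA character(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  idx - 1L
}

#' Reverse complement of an RNA sequence
#'
#' @param seq RNA string (alphabet A, C, G, U).
#' @return The reverse complement, 5'->3'.
#' @examples
#' rna_revcomp("GAUC")
#' @export
rna_revcomp <- function(seq) {
  if (nchar(seq) == 0) return("")
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  chars <- strsplit(toupper(seq), "")[[1]]
  if (!all(chars %in% names(comp))) {
    stop("invalid RNA alphabet in rna_revcomp", call. = FALSE)
  }
  paste(rev(unname(comp[chars])), collapse = "")
}

# DNA -> RNA transliteration with a notice; accepts mixed-case input
dna_to_rna <- function(seq, quiet = TRUE) {
  up <- toupper(seq)
  if (grepl("T", up, fixed = TRUE)) {
    if (!quiet) message("DNA input transliterated to RNA (T -> U)")
    up <- gsub("T", "U", up, fixed = TRUE)
  }
  up
}

# TRUE if base x can pair (Watson-Crick or GU wobble) with base y
can_pair <- function(x, y) {
  paste0(x, y) %in% c("GC", "CG", "AU", "UA", "GU", "UG")
}
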