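#' Specification for a synthetic switch library
#'
#' Describes the template geometry and orthogonality scheme used by
#' [make_switch_library()].  The defaults follow the second-generation
#' switch anatomy used throughout the package: 12-nt toehold, 18-bp
#' stem, 11-nt loop carrying the RBS, 21-nt linker to the reporter
#' frame.
#'
#' @param n_switches number of mutually orthogonal switches (>= 1).
#' @param toehold_len,stem_len,loop_len,linker_len segment lengths
#'   (nt).
#' @param orthogonality_scheme \code{"disjoint-kmer"} (default:
#'   sensing domains are additionally forbidden from sharing any
#'   complementary 6-mer, bounding Watson-Crick runs by construction)
#'   or \code{"random-screened"} (duplex-energy screening only).
#' @param crosstalk_max maximum tolerated non-cognate duplex energy
#'   (model units) between any trigger core and a non-cognate switch.
#' @param rbs RBS motif placed once in each loop.
#' @param seed integer seed; libraries are deterministic per seed.
#' @return An object of class \code{fixture_spec}.
#' @export
fixture_spec <- function(n_switches = 2L, toehold_len = 12L,
                         stem_len = 18L, loop_len = 11L,
                         linker_len = 21L,
                         orthogonality_scheme = c("disjoint-kmer",
                                                  "random-screened"),
                         crosstalk_max = -30, rbs = "AGGAGG",
                         seed = 1L) {
  orthogonality_scheme <- match.arg(orthogonality_scheme)
  stopifnot(n_switches >= 1, toehold_len >= 4, stem_len >= 6,
            loop_len >= nchar(rbs), linker_len >= 3)
  structure(
    list(n_switches = as.integer(n_switches),
         toehold_len = as.integer(toehold_len),
         stem_len = as.integer(stem_len),
         loop_len = as.integer(loop_len),
         linker_len = as.integer(linker_len),
         orthogonality_scheme = orthogonality_scheme,
         crosstalk_max = crosstalk_max, rbs = rbs,
         seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1), k:n)
}

#' Generate a synthetic library of orthogonal toehold switches
#'
#' Stand-ins for a characterised orthogonal switch collection: each
#' switch is drawn at random and kept only if it passes
#' [validate_switch()] and if its cognate trigger core hybridizes with
#' every previously accepted switch (and every previously accepted
#' trigger core with it) more weakly than the crosstalk threshold.
#' Under the \code{"disjoint-kmer"} scheme sensing domains must also
#' avoid sharing any complementary 6-mer.  Deterministic per seed.
#'
#' @param spec a [fixture_spec()].
#' @param model an [energy_model()].
#' @param max_tries candidate draws per switch before giving up.
#' @return Named list of [switch_part()]s (sw1, sw2, ...).
#' @export
make_switch_library <- function(spec = fixture_spec(),
                                model = energy_model(),
                                max_tries = 2000L) {
  cfg <- part_config(rbs = spec$rbs)
  pad <- function(n) random_rna(n, alphabet = c("A", "C"))
  with_seed(spec$seed, {
    switches <- list()
    cores <- character(0)
    for (k in seq_len(spec$n_switches)) {
      accepted <- FALSE
      for (try in seq_len(max_tries)) {
        toehold <- random_rna(spec$toehold_len)
        stem_bottom <- random_rna(spec$stem_len)
        pre <- (spec$loop_len - nchar(spec$rbs)) %/% 2
        loop <- paste0(pad(pre), spec$rbs,
                       pad(spec$loop_len - nchar(spec$rbs) - pre))
        linker <- paste0("AUG", pad(spec$linker_len - 3L))
        cand <- switch_part(paste0("sw", k), toehold_seq = toehold,
                            stem_bottom = stem_bottom,
                            stem_top = rna_revcomp(stem_bottom),
                            loop_seq = loop, linker_seq = linker,
                            start_codon_offset = 0L)
        if (!validate_switch(cand, cfg, model)$valid) next
        core <- rna_revcomp(sensing_domain(cand))
        if (spec$orthogonality_scheme == "disjoint-kmer" &&
            length(switches) > 0) {
          km <- kmers(core, 6L)
          clash <- any(vapply(switches, function(sw) {
            any(km %in% kmers(switch_sequence(sw), 6L))
          }, logical(1)))
          if (!clash) {
            km_old <- unlist(lapply(cores, kmers, k = 6L))
            clash <- any(kmers(switch_sequence(cand), 6L) %in% km_old)
          }
          if (clash) next
        }
        ortho <- TRUE
        for (j in seq_along(switches)) {
          e1 <- duplex_energy(core, switch_sequence(switches[[j]]),
                              model)$energy
          e2 <- duplex_energy(cores[j], switch_sequence(cand),
                              model)$energy
          if (e1 < spec$crosstalk_max || e2 < spec$crosstalk_max) {
            ortho <- FALSE
            break
          }
        }
        if (!ortho) next
        switches[[cand$name]] <- cand
        cores <- c(cores, core)
        accepted <- TRUE
        break
      }
      if (!accepted) {
        stop(sprintf(
          "could not generate switch %d of %d after %d tries; consider a weaker crosstalk threshold or larger alphabet spread",
          k, spec$n_switches, max_tries), call. = FALSE)
      }
    }
    switches
  })
}

#' Generate a decoy RNA orthogonal to an entire part set
#'
#' A decoy interacts with nothing: its duplex energy against every
#' supplied species stays above (weaker than) the crosstalk threshold.
#' Used as a negative control in simulations.
#'
#' @param library list of parts (switches, triggers, antisenses).
#' @param seed integer seed.
#' @param length decoy length in nt (> 0).
#' @param model an [energy_model()].
#' @param crosstalk_max duplex-energy threshold, model units.
#' @param max_tries candidate draws before giving up.
#' @return An object of class \code{decoy_rna} (name, seq).
#' @export
make_decoy <- function(library, seed = 1L, length = 30L,
                       model = energy_model(), crosstalk_max = -30,
                       max_tries = 5000L) {
  if (length(library) == 0) stop("library must be non-empty", call. = FALSE)
  if (length <= 0) {
    stop("decoy length must be positive", call. = FALSE)
  }
  seqs <- vapply(library, rna_sequence, character(1))
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      cand <- random_rna(length)
      ok <- all(vapply(seqs, function(s) {
        duplex_energy(cand, s, model)$energy > crosstalk_max
      }, logical(1)))
      if (ok) {
        return(structure(list(name = "decoy", seq = cand),
                         class = "decoy_rna"))
      }
    }
    stop(sprintf("decoy search failed after %d tries", max_tries),
         call. = FALSE)
  })
}

#' @export
print.decoy_rna <- function(x, ...) {
  cat(sprintf("decoy RNA '%s' (%d nt)\n", x$name, nchar(x$seq)))
  invisible(x)
}
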