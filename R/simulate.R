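#' Expression and readout parameters for circuit simulation
#'
#' Concentrations are in arbitrary relative units.  Transcript
#' abundance of a species is \code{copy_scale[plasmid] * (leak +
#' (1 - leak) * theta)} with a Hill induction function
#' \code{theta = c^n / (K^n + c^n)}; constitutive and unwired species
#' have \code{theta = 1}.  Duplex energies are converted to
#' association constants by \code{K = exp((dG_ref - dG) /
#' energy_scale)}, calibrated so that a full-length cognate duplex
#' sits deep in the strong-binding regime (K * total >> 1) while the
#' incidental few-base-pair complementarity expected between random
#' sequences stays weakly bound (K * total << 1).
#'
#' @param copy_scale named numeric: relative transcript abundance per
#'   plasmid copy level.
#' @param leak_fraction transcriptional leak of a repressed operator.
#' @param hill_K inducer concentration at half-maximal induction.
#' @param hill_n Hill coefficient.
#' @param on_conc inducer concentration used for logical 1.
#' @param reporter_gain,reporter_basal linear readout map: level =
#'   basal + gain * active fraction.
#' @param energy_scale,dG_ref energy-to-association-constant
#'   conversion (model units).
#' @param threshold absolute ON/OFF threshold for Boolean calls; NULL
#'   (default) calibrates the geometric mean of the ON and OFF levels
#'   of a reference BUFFER gate built from the netlist's first switch.
#' @param digitality_ratio required ratio of single-inducer-edge to
#'   corner output for a digital XOR response surface.
#' @param t7_induced master transcription switch (the T7 polymerase
#'   induction); FALSE silences every species.
#' @param tol relative convergence tolerance of the equilibrium
#'   solver.
#' @param max_iter maximum solver iterations.
#' @return An object of class \code{expression_params}.
#' @export
expression_params <- function(copy_scale = c(low = 1, medium = 3, high = 9),
                              leak_fraction = 0.02,
                              hill_K = 10, hill_n = 2, on_conc = 100,
                              reporter_gain = 100, reporter_basal = 1,
                              energy_scale = 3, dG_ref = -60,
                              threshold = NULL, digitality_ratio = 10,
                              t7_induced = TRUE,
                              tol = 1e-12, max_iter = 50000L) {
  stopifnot(all(copy_scale > 0), leak_fraction >= 0, leak_fraction < 1,
            hill_n > 0, hill_K > 0, energy_scale > 0)
  structure(
    list(copy_scale = copy_scale, leak_fraction = leak_fraction,
         hill_K = hill_K, hill_n = hill_n, on_conc = on_conc,
         reporter_gain = reporter_gain, reporter_basal = reporter_basal,
         energy_scale = energy_scale, dG_ref = dG_ref,
         threshold = threshold, digitality_ratio = digitality_ratio,
         t7_induced = t7_induced, tol = tol,
         max_iter = as.integer(max_iter)),
    class = "expression_params"
  )
}

hill_theta <- function(conc, params) {
  if (conc < 0) stop("negative inducer concentration", call. = FALSE)
  if (conc == 0) return(0)
  conc^params$hill_n / (params$hill_K^params$hill_n + conc^params$hill_n)
}

assoc_constant <- function(dG, params) {
  exp(pmin((params$dG_ref - dG) / params$energy_scale, 500))
}

#' Transcript abundances of netlist species at given inducer levels
#'
#' @param netlist a wired, plasmid-assigned [circuit_netlist()].
#' @param inducer_concs named numeric vector of inducer
#'   concentrations (missing inducers are 0).
#' @param params an [expression_params()].
#' @return Named numeric vector species -> relative abundance.
#' @export
transcription_levels <- function(netlist, inducer_concs = numeric(0),
                                 params = expression_params()) {
  if (length(netlist$plasmids) == 0) {
    stop("netlist has no plasmid assignment; call assign_plasmids()",
         call. = FALSE)
  }
  op_to_ind <- stats::setNames(names(netlist$inducer_map),
                               unname(netlist$inducer_map))
  theta_of <- function(sp) {
    op <- sp$operator %||% "none"
    if (op %in% c("none", "constitutive")) return(1)
    ind <- op_to_ind[[op]]
    if (is.null(ind)) return(1)
    conc <- if (ind %in% names(inducer_concs)) inducer_concs[[ind]] else 0
    hill_theta(conc, params)
  }
  species <- c(netlist$switches, netlist$triggers, netlist$antisenses)
  ab <- vapply(species, function(sp) {
    scale <- params$copy_scale[[netlist$plasmids[[sp$name]]]]
    th <- theta_of(sp)
    wired <- !(sp$operator %||% "none") %in% c("none", "constitutive")
    if (wired) {
      scale * (params$leak_fraction + (1 - params$leak_fraction) * th)
    } else {
      scale * th
    }
  }, numeric(1))
  if (!params$t7_induced) ab[] <- 0
  ab
}

#' Solve the competitive hybridization equilibrium
#'
#' Simultaneous mass-action binding equilibria S + T <-> S.T and
#' T + A <-> T.A over all switch sensor sites, triggers and
#' antisenses, with association constants from pairwise duplex
#' energies.  Solved by a damped fixed-point iteration on the free
#' concentrations; the unique non-negative solution satisfies every
#' conservation total to the requested tolerance.  Antisense
#' annihilation by direct hybridization and by strand displacement of
#' switch-bound trigger reach the same final state, so both are
#' subsumed in the equilibrium.
#'
#' @param totals list with named numeric vectors \code{S} (sensor
#'   sites), \code{T} (triggers), \code{A} (antisenses).
#' @param dG list with matrices \code{ST} (sites x triggers) and
#'   \code{TA} (triggers x antisenses) of duplex energies; ignored if
#'   \code{K} is given.
#' @param params an [expression_params()].
#' @param K optional list of association-constant matrices \code{ST},
#'   \code{TA}, overriding the energy conversion.
#' @return An object of class \code{equilibrium_state}: free
#'   concentrations \code{S}, \code{T}, \code{A}, complex matrices
#'   \code{ST}, \code{TA}, \code{residual} and \code{iterations}.
#' @export
solve_equilibrium <- function(totals, dG = NULL,
                              params = expression_params(), K = NULL) {
  S_tot <- totals$S %||% numeric(0)
  T_tot <- totals$T %||% numeric(0)
  A_tot <- totals$A %||% numeric(0)
  if (any(c(S_tot, T_tot, A_tot) < 0)) {
    stop("abundances must be non-negative", call. = FALSE)
  }
  ns <- length(S_tot); nt <- length(T_tot); na <- length(A_tot)
  if (is.null(K)) {
    K <- list(
      ST = if (ns > 0 && nt > 0) assoc_constant(dG$ST, params)
           else matrix(0, ns, nt),
      TA = if (nt > 0 && na > 0) assoc_constant(dG$TA, params)
           else matrix(0, nt, na))
  }
  K_ST <- matrix(K$ST %||% 0, ns, nt)
  K_TA <- matrix(K$TA %||% 0, nt, na)
  if (any(!is.finite(K_ST)) || any(!is.finite(K_TA))) {
    stop("association constants must be finite", call. = FALSE)
  }
  s <- S_tot; t <- T_tot; a <- A_tot
  iter <- 0L
  repeat {
    iter <- iter + 1L
    s_new <- if (ns > 0) S_tot / (1 + as.vector(K_ST %*% t)) else s
    a_new <- if (na > 0) A_tot / (1 + as.vector(crossprod(K_TA, t)))
             else a
    denom_t <- 1 +
      (if (ns > 0) as.vector(crossprod(K_ST, s_new)) else 0) +
      (if (na > 0) as.vector(K_TA %*% a_new) else 0)
    t_prop <- if (nt > 0) T_tot / denom_t else t
    # geometric damping stabilises the strongly bound regime
    t_new <- sqrt(pmax(t, 1e-300) * pmax(t_prop, 1e-300))
    t_new[T_tot == 0] <- 0
    delta <- max(abs(c(s_new - s, a_new - a, t_new - t)) /
                   pmax(c(s_new, a_new, t_new), 1e-12), 0)
    s <- s_new; a <- a_new; t <- t_new
    if (delta < params$tol || iter >= params$max_iter) break
  }
  # polish: recompute s, a exactly for the final t
  s <- if (ns > 0) S_tot / (1 + as.vector(K_ST %*% t)) else s
  a <- if (na > 0) A_tot / (1 + as.vector(crossprod(K_TA, t))) else a
  ST <- if (ns > 0 && nt > 0) K_ST * outer(s, t) else matrix(0, ns, nt)
  TA <- if (nt > 0 && na > 0) K_TA * outer(t, a) else matrix(0, nt, na)
  res_S <- if (ns > 0) abs(s + rowSums(ST) - S_tot) / pmax(S_tot, 1e-12)
           else 0
  res_T <- if (nt > 0) abs(t + colSums(ST) + rowSums(TA) - T_tot) /
             pmax(T_tot, 1e-12) else 0
  res_A <- if (na > 0) abs(a + colSums(TA) - A_tot) / pmax(A_tot, 1e-12)
           else 0
  residual <- max(res_S, res_T, res_A)
  if (iter >= params$max_iter && residual > 1e-6) {
    stop(sprintf("equilibrium solver did not converge (residual %.3g after %d iterations)",
                 residual, iter), call. = FALSE)
  }
  dimnames(ST) <- list(names(S_tot), names(T_tot))
  dimnames(TA) <- list(names(T_tot), names(A_tot))
  structure(
    list(S = stats::setNames(s, names(S_tot)),
         T = stats::setNames(t, names(T_tot)),
         A = stats::setNames(a, names(A_tot)),
         ST = ST, TA = TA, residual = residual, iterations = iter,
         totals = list(S = S_tot, T = T_tot, A = A_tot)),
    class = "equilibrium_state"
  )
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat(sprintf("equilibrium state: %d site(s), %d trigger(s), %d antisense(s); residual %.2g (%d iterations)\n",
              length(x$S), length(x$T), length(x$A), x$residual,
              x$iterations))
  invisible(x)
}

# sensor-site bookkeeping: each sensor of each switch is a binding
# site whose total equals the switch abundance
netlist_sites <- function(netlist) {
  sites <- list()
  for (sw in netlist$switches) {
    n_sensors <- if (inherits(sw, "concatenated_switch")) {
      length(sw$sensors)
    } else {
      1L
    }
    for (k in seq_len(n_sensors)) {
      sensor <- if (inherits(sw, "concatenated_switch")) {
        sw$sensors[[k]]
      } else {
        sw
      }
      sites[[paste0(sw$name, "#", k)]] <-
        list(switch = sw$name, sensor_index = k, part = sensor)
    }
  }
  sites
}

#' Pairwise duplex energies needed to simulate a netlist
#'
#' Computes the site-by-trigger and trigger-by-antisense duplex-energy
#' matrices for the equilibrium model.  Each sensor of a concatenated
#' switch is treated as an independent binding site folded in its own
#' hairpin context.
#'
#' @param netlist a [circuit_netlist()].
#' @param model an [energy_model()].
#' @return list(ST, TA) of energy matrices (model units).
#' @export
netlist_energies <- function(netlist, model = energy_model()) {
  sites <- netlist_sites(netlist)
  tr <- netlist$triggers
  an <- netlist$antisenses
  ST <- matrix(0, length(sites), length(tr),
               dimnames = list(names(sites), names(tr)))
  for (i in seq_along(sites)) {
    site_seq <- switch_sequence(sites[[i]]$part)
    for (j in seq_along(tr)) {
      ST[i, j] <- duplex_energy(rna_sequence(tr[[j]]), site_seq,
                                model)$energy
    }
  }
  TA <- matrix(0, length(tr), length(an),
               dimnames = list(names(tr), names(an)))
  for (i in seq_along(tr)) {
    for (j in seq_along(an)) {
      TA[i, j] <- duplex_energy(rna_sequence(tr[[i]]),
                                rna_sequence(an[[j]]), model)$energy
    }
  }
  list(ST = ST, TA = TA)
}

#' Solve a netlist's equilibrium at given inducer concentrations
#'
#' Convenience wrapper: computes transcript abundances with
#' [transcription_levels()], lays out sensor binding sites and solves
#' the competitive hybridization equilibrium.
#'
#' @param netlist a wired, plasmid-assigned [circuit_netlist()].
#' @param inducer_concs named numeric vector of inducer concentrations.
#' @param params an [expression_params()].
#' @param model an [energy_model()].
#' @param energies optional precomputed [netlist_energies()] (avoids
#'   refolding when solving many conditions).
#' @return An \code{equilibrium_state}; pass to [readout()].
#' @export
simulate_state <- function(netlist, inducer_concs,
                           params = expression_params(),
                           model = energy_model(), energies = NULL) {
  ab <- transcription_levels(netlist, inducer_concs, params)
  sites <- netlist_sites(netlist)
  S_tot <- vapply(sites, function(s) ab[[s$switch]], numeric(1))
  T_tot <- ab[names(netlist$triggers)]
  A_tot <- if (length(netlist$antisenses) > 0) {
    ab[names(netlist$antisenses)]
  } else {
    stats::setNames(numeric(0), character(0))
  }
  energies <- energies %||% netlist_energies(netlist, model)
  solve_equilibrium(list(S = S_tot, T = T_tot, A = A_tot), energies,
                    params)
}

#' Reporter readout from an equilibrium state
#'
#' The active fraction of a switch is computed from the triggered
#' fraction of its sensor sites: a single sensor reports its own
#' occupancy; an OR-type concatenated switch is active when at least
#' one sensor is triggered (1 - prod(1 - p)); an AND-type two-trigger
#' sensor requires all sensors bound (prod(p)).  Reporter level =
#' basal + gain * active fraction.
#'
#' @param state an \code{equilibrium_state} from a netlist solve.
#' @param netlist the [circuit_netlist()] it came from.
#' @param params an [expression_params()].
#' @return Named numeric vector reporter channel -> level.
#' @export
readout <- function(state, netlist, params = expression_params()) {
  sites <- netlist_sites(netlist)
  occupancy <- vapply(seq_along(sites), function(i) {
    tot <- state$totals$S[[i]]
    if (tot <= 0) return(0)
    sum(state$ST[i, ]) / tot
  }, numeric(1))
  names(occupancy) <- names(sites)
  out <- numeric(0)
  for (sw in netlist$switches) {
    idx <- which(vapply(sites, function(s) s$switch == sw$name,
                        logical(1)))
    p <- occupancy[idx]
    logic <- if (inherits(sw, "concatenated_switch")) sw$logic else "OR"
    frac <- if (logic == "AND") prod(p) else 1 - prod(1 - p)
    ch <- netlist$reporters[[sw$name]] %||% sw$reporter
    out[ch] <- params$reporter_basal + params$reporter_gain * frac
  }
  out
}

# reference BUFFER calibration: closed-form two-species binding of the
# netlist's first sensor site and its cognate trigger, at full
# induction (ON) and at transcriptional leak (OFF); the Boolean
# threshold is their geometric mean
calibrate_threshold <- function(netlist, params = expression_params(),
                                model = energy_model(), energies = NULL) {
  energies <- energies %||% netlist_energies(netlist, model)
  e <- netlist$edges
  act <- e[e$type == "activates", , drop = FALSE]
  if (nrow(act) == 0) stop("netlist has no activation edges", call. = FALSE)
  site <- paste0(act$to[1], "#", act$sensor[1])
  K <- assoc_constant(energies$ST[site, act$from[1]], params)
  S <- params$copy_scale[["low"]]
  T_on <- params$copy_scale[["medium"]]
  T_off <- params$copy_scale[["medium"]] * params$leak_fraction
  two_species <- function(S, T, K) {
    b <- S + T + 1 / K
    ((b - sqrt(b^2 - 4 * S * T)) / 2)
  }
  lvl <- function(T) {
    params$reporter_basal +
      params$reporter_gain * two_species(S, T, K) / S
  }
  sqrt(lvl(T_on) * lvl(T_off))
}

#' Predicted truth table of a compiled circuit
#'
#' Evaluates the full equilibrium model at every combination of
#' inducers (0 or \code{on_conc}) and converts reporter levels to
#' Boolean calls against the calibrated (or overridden) threshold.
#'
#' @param netlist a wired, plasmid-assigned [circuit_netlist()].
#' @param params an [expression_params()].
#' @param model an [energy_model()].
#' @param on_concs named numeric vector of logical-1 concentrations
#'   per inducer (default \code{on_conc} for each).
#' @return A data.frame of class \code{truth_table_result}: one row
#'   per input combination with inducer bits, reporter levels, Boolean
#'   calls and margins (level / threshold).
#' @export
truth_table <- function(netlist, params = expression_params(),
                        model = energy_model(), on_concs = NULL) {
  inducers <- names(netlist$inducer_map)
  if (length(inducers) == 0) {
    stop("netlist is not wired; call wire_inducers()", call. = FALSE)
  }
  if (is.null(on_concs)) {
    on_concs <- stats::setNames(rep(params$on_conc, length(inducers)),
                                inducers)
  }
  energies <- netlist_energies(netlist, model)
  threshold <- params$threshold %||%
    calibrate_threshold(netlist, params, model, energies)
  combos <- expand.grid(rep(list(c(0L, 1L)), length(inducers)),
                        KEEP.OUT.ATTRS = FALSE)
  names(combos) <- inducers
  rows <- lapply(seq_len(nrow(combos)), function(r) {
    bits <- unlist(combos[r, , drop = FALSE])
    concs <- stats::setNames(ifelse(bits == 1L,
                                    on_concs[inducers], 0), inducers)
    state <- simulate_state(netlist, concs, params, model, energies)
    levels <- readout(state, netlist, params)
    row <- as.list(bits)
    for (ch in names(levels)) {
      row[[paste0("level_", ch)]] <- unname(levels[[ch]])
      row[[paste0("call_", ch)]] <- unname(levels[[ch]] >= threshold)
      row[[paste0("margin_", ch)]] <- unname(levels[[ch]] / threshold)
    }
    as.data.frame(row)
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- threshold
  attr(out, "inducers") <- inducers
  class(out) <- c("truth_table_result", "data.frame")
  out
}

#' @export
print.truth_table_result <- function(x, ...) {
  cat(sprintf("truth table (threshold %.3g):\n", attr(x, "threshold")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Reporter response surface over an inducer concentration grid
#'
#' Evaluates the equilibrium model over the Cartesian grid of two
#' inducer concentration vectors, returning the reporter level matrix
#' (rows: first inducer, columns: second).  For an XOR circuit the
#' surface is high along the single-inducer edges and low at the
#' (0,0) and (max,max) corners.
#'
#' @param netlist a wired, plasmid-assigned [circuit_netlist()].
#' @param grid named list of two non-empty, non-negative
#'   concentration vectors; names must match the netlist inducers.
#' @param params an [expression_params()].
#' @param model an [energy_model()].
#' @param reporter channel to report (default: first).
#' @return Numeric matrix of reporter levels with concentration
#'   dimnames.
#' @export
dose_grid <- function(netlist, grid, params = expression_params(),
                      model = energy_model(), reporter = NULL) {
  stopifnot(length(grid) == 2, all(lengths(grid) > 0))
  if (any(unlist(grid) < 0)) {
    stop("inducer concentrations must be non-negative", call. = FALSE)
  }
  ind <- names(grid)
  stopifnot(all(ind %in% names(netlist$inducer_map)))
  energies <- netlist_energies(netlist, model)
  m <- matrix(NA_real_, length(grid[[1]]), length(grid[[2]]),
              dimnames = list(grid[[1]], grid[[2]]))
  for (i in seq_along(grid[[1]])) {
    for (j in seq_along(grid[[2]])) {
      concs <- stats::setNames(c(grid[[1]][i], grid[[2]][j]), ind)
      state <- simulate_state(netlist, concs, params, model, energies)
      levels <- readout(state, netlist, params)
      if (is.null(reporter)) reporter <- names(levels)[1]
      m[i, j] <- levels[[reporter]]
    }
  }
  m
}

#' Digitality of an XOR dose-response surface
#'
#' Ratio of the maximum single-inducer-edge output to the maximum of
#' the two "both-low"/"both-high" corners of a dose grid; a digital
#' XOR response keeps this at or above the configured ratio.
#'
#' @param m matrix from [dose_grid()].
#' @return The edge-to-corner ratio.
#' @export
xor_digitality <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  edge <- max(m[1, nc], m[nr, 1])
  corner <- max(m[1, 1], m[nr, nc])
  edge / corner
}
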