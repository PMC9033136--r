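#' Write a part library to FASTA
#'
#' Parts are serialised as one FASTA record per species.  The header
#' carries the part role and segmentation as \code{key=value} tokens, so
#' the file round-trips through [load_part_library()] bit-exactly.  A
#' YAML sidecar (same path plus \code{.yaml}) with per-record metadata
#' is written when \code{sidecar = TRUE}.
#'
#' @param parts list of parts ([switch_part()], [trigger_rna()],
#'   [antisense_rna()], [concatenated_switch()]).
#' @param path output FASTA path.
#' @param sidecar also write a YAML metadata sidecar.
#' @return Invisibly, \code{path}.
#' @export
write_part_library <- function(parts, path, sidecar = FALSE) {
  headers <- vapply(parts, part_header, character(1))
  seqs <- vapply(parts, rna_sequence, character(1))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- headers
  Biostrings::writeXStringSet(set, filepath = path, width = 70)
  if (sidecar) {
    meta <- lapply(parts, part_metadata)
    names(meta) <- vapply(parts, function(p) p$name, character(1))
    yaml::write_yaml(meta, paste0(path, ".yaml"))
  }
  invisible(path)
}

part_role <- function(p) {
  if (inherits(p, "switch_part")) "switch"
  else if (inherits(p, "concatenated_switch")) "concatenated_switch"
  else if (inherits(p, "trigger_rna")) "trigger"
  else if (inherits(p, "antisense_rna")) "antisense"
  else if (inherits(p, "decoy_rna")) "decoy"
  else stop("unknown part class", call. = FALSE)
}

part_metadata <- function(p) {
  role <- part_role(p)
  m <- list(role = role)
  if (role == "switch") {
    m$toehold_len <- nchar(p$toehold_seq)
    m$stem_len <- nchar(p$stem_bottom)
    m$loop_len <- nchar(p$loop_seq)
    m$linker_len <- nchar(p$linker_seq)
    m$start_codon_offset <- p$start_codon_offset
    m$reporter <- p$reporter
  } else if (role %in% c("trigger", "antisense")) {
    m$overhang5_len <- nchar(p$overhang5)
    m$core_len <- nchar(p$core_seq)
    m$overhang3_len <- nchar(p$overhang3)
    m$operator <- p$operator
    if (nrow(p$bulges) > 0) {
      m$bulges <- paste(sprintf("%d:%s", p$bulges$position, p$bulges$base),
                        collapse = ",")
    }
    if (role == "antisense") m$target_trigger <- p$target_trigger
    if (role == "trigger" && !is.null(p$cognate_switch)) {
      m$cognate_switch <- p$cognate_switch
    }
  } else if (role == "concatenated_switch") {
    m$logic <- p$logic
    m$reporter <- p$reporter
    m$linker_len <- nchar(p$linker_between_sensors)
    m$sensors <- paste(vapply(p$sensors, function(s) s$name, character(1)),
                       collapse = ",")
  }
  m
}

part_header <- function(p) {
  m <- part_metadata(p)
  toks <- paste(names(m), unlist(m), sep = "=")
  paste(c(p$name, toks), collapse = " ")
}

#' Load a part library from FASTA
#'
#' Reads a FASTA written by [write_part_library()] (or hand-annotated
#' with the same \code{key=value} header tokens), reconstructing typed
#' parts.  DNA input (containing T) is transliterated to RNA with a
#' notice.  A YAML sidecar at \code{<path>.yaml}, if present, supplies
#' or overrides per-record metadata.
#'
#' @param path FASTA path.
#' @param quiet suppress the DNA-to-RNA notice.
#' @return Named list of typed parts.
#' @export
load_part_library <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  sidecar_path <- paste0(path, ".yaml")
  sidecar <- if (file.exists(sidecar_path)) {
    yaml::read_yaml(sidecar_path)
  } else {
    list()
  }
  parts <- vector("list", length(set))
  nms <- character(length(set))
  for (k in seq_along(set)) {
    header <- names(set)[k]
    toks <- strsplit(trimws(header), "\\s+")[[1]]
    name <- toks[1]
    meta <- parse_kv_tokens(toks[-1])
    if (name %in% names(sidecar)) {
      for (key in names(sidecar[[name]])) meta[[key]] <- sidecar[[name]][[key]]
    }
    seq <- as.character(set[[k]])
    seq <- dna_to_rna(seq, quiet = quiet)
    if (!grepl("^[ACGU]+$", seq)) {
      stop(sprintf("record '%s': sequence contains non-ACGU/T characters",
                   name), call. = FALSE)
    }
    if (is.null(meta$role)) {
      stop(sprintf("record '%s': missing role annotation", name),
           call. = FALSE)
    }
    parts[[k]] <- part_from_record(name, seq, meta)
    nms[k] <- name
  }
  names(parts) <- nms
  parts
}

parse_kv_tokens <- function(toks) {
  kv <- toks[grepl("=", toks, fixed = TRUE)]
  out <- list()
  for (t in kv) {
    eq <- regexpr("=", t, fixed = TRUE)
    out[[substr(t, 1, eq - 1)]] <- substr(t, eq + 1, nchar(t))
  }
  out
}

parse_bulges <- function(spec) {
  if (is.null(spec) || !nzchar(spec)) return(empty_bulges())
  items <- strsplit(spec, ",", fixed = TRUE)[[1]]
  pos <- as.integer(sub(":.*", "", items))
  base <- sub(".*:", "", items)
  data.frame(position = pos, base = base, stringsAsFactors = FALSE)
}

part_from_record <- function(name, seq, meta) {
  role <- meta$role
  num <- function(key, default = NULL) {
    v <- meta[[key]]
    if (is.null(v)) {
      if (is.null(default)) {
        stop(sprintf("record '%s': missing required field '%s'", name, key),
             call. = FALSE)
      }
      default
    } else {
      as.integer(v)
    }
  }
  if (role == "switch") {
    tl <- num("toehold_len"); sl <- num("stem_len")
    ll <- num("loop_len"); kl <- num("linker_len")
    if (tl + 2 * sl + ll + kl != nchar(seq)) {
      stop(sprintf("record '%s': segment lengths do not add up to sequence length",
                   name), call. = FALSE)
    }
    ofs <- c(0, cumsum(c(tl, sl, ll, sl)))
    seg <- function(i, len) substr(seq, ofs[i] + 1, ofs[i] + len)
    switch_part(name,
                toehold_seq = seg(1, tl), stem_bottom = seg(2, sl),
                loop_seq = seg(3, ll), stem_top = seg(4, sl),
                linker_seq = substr(seq, ofs[5] + 1, nchar(seq)),
                start_codon_offset = num("start_codon_offset", 0L),
                reporter = meta$reporter %||% "green")
  } else if (role %in% c("trigger", "antisense")) {
    o5 <- num("overhang5_len"); cl <- num("core_len")
    bulges <- parse_bulges(meta$bulges)
    comp <- disassemble_rna(seq, o5, cl, bulges)
    if (role == "trigger") {
      trigger_rna(name, core_seq = comp$core_seq,
                  overhang5 = comp$overhang5, overhang3 = comp$overhang3,
                  bulges = bulges, operator = meta$operator %||% "none",
                  cognate_switch = meta$cognate_switch)
    } else {
      if (is.null(meta$target_trigger)) {
        stop(sprintf("record '%s': antisense missing target_trigger", name),
             call. = FALSE)
      }
      antisense_rna(name, target_trigger = meta$target_trigger,
                    core_seq = comp$core_seq, overhang5 = comp$overhang5,
                    overhang3 = comp$overhang3, bulges = bulges,
                    operator = meta$operator %||% "none")
    }
  } else if (role == "decoy") {
    structure(list(name = name, seq = seq), class = "decoy_rna")
  } else {
    stop(sprintf("record '%s': unknown role '%s'", name, role),
         call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
rna_sequence.decoy_rna <- function(x) x$seq

#' Export an expression cassette as a GenBank-style flat file
#'
#' Writes an annotated record per species of a netlist: T7 promoter,
#' operator (if wired), and the anatomical features of the RNA part
#' (toehold/stem/loop/linker for switches; overhangs/bulges/core for
#' triggers and antisenses).  Coordinates in the FEATURES table are
#' 1-based inclusive, per flat-file convention.
#'
#' @param netlist a [circuit_netlist()].
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
write_cassette_genbank <- function(netlist, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in c(netlist$switches, netlist$triggers, netlist$antisenses)) {
    seq <- rna_sequence(p)
    n <- nchar(seq)
    writeLines(sprintf("LOCUS       %-16s %d bp    RNA     linear",
                       p$name, n), con)
    writeLines(sprintf("DEFINITION  %s cassette (%s).", p$name,
                       part_role(p)), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    feat <- function(key, from, to, label) {
      writeLines(sprintf("     %-15s %d..%d", key, from, to), con)
      writeLines(sprintf("                     /label=\"%s\"", label), con)
    }
    writeLines("     promoter        <1..1", con)
    writeLines("                     /label=\"T7 promoter (upstream)\"", con)
    op <- if (!is.null(p$operator) && !p$operator %in% c("none")) p$operator
    if (!is.null(op)) {
      writeLines(sprintf("                     /note=\"%s operator upstream of transcript\"",
                         op), con)
    }
    if (inherits(p, "switch_part")) {
      tl <- nchar(p$toehold_seq); sl <- nchar(p$stem_bottom)
      ll <- nchar(p$loop_seq)
      feat("misc_feature", 1, tl, "toehold")
      feat("stem_loop", tl + 1, tl + 2 * sl + ll, "switch hairpin")
      feat("RBS", tl + sl + 1, tl + sl + ll, "loop (contains RBS)")
      feat("misc_feature", tl + 2 * sl + ll + 1, n, "linker to reporter")
    } else if (inherits(p, "concatenated_switch")) {
      pos <- 1
      for (s in p$sensors) {
        len <- nchar(switch_sequence(s))
        tl <- nchar(s$toehold_seq); sl <- nchar(s$stem_bottom)
        ll <- nchar(s$loop_seq)
        feat("misc_feature", pos, pos + len - 1,
             sprintf("sensor %s", s$name))
        feat("misc_feature", pos, pos + tl - 1,
             sprintf("toehold (%s)", s$name))
        feat("stem_loop", pos + tl, pos + tl + 2 * sl + ll - 1,
             sprintf("switch hairpin (%s)", s$name))
        feat("RBS", pos + tl + sl, pos + tl + sl + ll - 1,
             sprintf("loop with RBS (%s)", s$name))
        pos <- pos + len + nchar(p$linker_between_sensors)
        if (pos - nchar(p$linker_between_sensors) <= n &&
            nchar(p$linker_between_sensors) > 0 &&
            !identical(s$name, p$sensors[[length(p$sensors)]]$name)) {
          feat("misc_feature", pos - nchar(p$linker_between_sensors),
               pos - 1, "inter-sensor linker")
        }
      }
    } else if (inherits(p, "trigger_rna") || inherits(p, "antisense_rna")) {
      o5 <- nchar(p$overhang5); o3 <- nchar(p$overhang3)
      if (o5 > 0) feat("misc_feature", 1, o5, "5' overhang")
      core_start <- o5 + sum(p$bulges$position < o5 + 1) + 1
      feat("misc_feature", core_start, core_start + nchar(p$core_seq) - 1,
           "core")
      if (o3 > 0) feat("misc_feature", n - o3 + 1, n, "3' overhang")
      for (k in seq_len(nrow(p$bulges))) {
        feat("misc_feature", p$bulges$position[k] + 1,
             p$bulges$position[k] + 1, "bulge")
      }
    }
    writeLines("ORIGIN", con)
    for (start in seq(1, n, by = 60)) {
      chunk <- substr(seq, start, min(start + 59, n))
      blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                          pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      writeLines(sprintf("%9d %s", start,
                         paste(tolower(blocks), collapse = " ")), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Serialise a netlist to JSON
#'
#' @param netlist a [circuit_netlist()].
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_netlist_json <- function(netlist, path) {
  ser_part <- function(p) {
    m <- part_metadata(p)
    m$name <- p$name
    m$sequence <- rna_sequence(p)
    if (inherits(p, "switch_part")) {
      m[c("toehold_seq", "stem_bottom", "stem_top", "loop_seq",
          "linker_seq")] <-
        p[c("toehold_seq", "stem_bottom", "stem_top", "loop_seq",
            "linker_seq")]
    } else if (!inherits(p, "concatenated_switch")) {
      m[c("core_seq", "overhang5", "overhang3")] <-
        p[c("core_seq", "overhang5", "overhang3")]
    }
    m
  }
  obj <- list(
    logic = netlist$logic,
    switches = lapply(netlist$switches, function(p) {
      if (inherits(p, "concatenated_switch")) {
        m <- ser_part(p)
        m$sensor_parts <- lapply(p$sensors, ser_part)
        m$linker_between_sensors <- p$linker_between_sensors
        m
      } else {
        ser_part(p)
      }
    }),
    triggers = lapply(netlist$triggers, ser_part),
    antisenses = lapply(netlist$antisenses, ser_part),
    edges = netlist$edges,
    plasmids = as.list(netlist$plasmids),
    inducer_map = as.list(netlist$inducer_map),
    reporters = as.list(netlist$reporters)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a netlist from JSON
#'
#' @param path JSON path written by [write_netlist_json()].
#' @return A [circuit_netlist()].
#' @export
read_netlist_json <- function(path) {
  obj <- jsonlite::read_json(path)
  de_part <- function(m) {
    part_from_record(m$name, m$sequence,
                     m[setdiff(names(m), c("name", "sequence"))])
  }
  switches <- lapply(obj$switches, function(m) {
    if (identical(m$role, "concatenated_switch")) {
      sensors <- lapply(m$sensor_parts, de_part)
      concatenated_switch(sensors,
                          linker_between_sensors = m$linker_between_sensors,
                          reporter = m$reporter, logic = m$logic,
                          name = m$name)
    } else {
      de_part(m)
    }
  })
  edges <- if (length(obj$edges) > 0) {
    do.call(rbind, lapply(obj$edges, function(e) {
      data.frame(from = e$from, to = e$to, type = e$type,
                 sensor = if (is.null(e$sensor)) NA_integer_
                          else as.integer(e$sensor),
                 stringsAsFactors = FALSE)
    }))
  } else {
    NULL
  }
  circuit_netlist(
    switches = switches,
    triggers = lapply(obj$triggers, de_part),
    antisenses = lapply(obj$antisenses, de_part),
    edges = edges,
    plasmids = unlist(obj$plasmids) %||% character(0),
    inducer_map = unlist(obj$inducer_map) %||% character(0),
    reporters = unlist(obj$reporters) %||% character(0),
    logic = obj$logic %||% NA_character_
  )
}
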