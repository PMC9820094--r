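# BiFC feasibility prediction: given an oligomer arrangement and a fusion-tag
# experiment (one VN-like and one VC-like fragment of a split fluorescent
# protein), decide whether the two fragments can meet and reconstitute a
# fluorophore.  A fragment pair can complement when the distance between
# their anchors does not exceed the sum of the two tether reaches plus the
# diameter of the reconstituted fluorophore, and the fluorophore disk can be
# placed somewhere on the inner half of the anchor-anchor segment without
# interpenetrating any MPM domain disk (tethers are flexible, so the
# fluorophore need not sit exactly at the midpoint).

# Candidate fluorophore placements along the anchor-anchor segment.
.fp_placement_fracs <- seq(0.25, 0.75, by = 0.125)

#' Define a BiFC fusion experiment
#'
#' @param id Experiment label.
#' @param tags List of tags, each `list(construct =, anchor =, fragment =)`
#'   with anchor in `N_term`, `C_term`, `loop3` and fragment in `VN`, `VC`,
#'   `GC`.  Exactly one VN-like (`VN`) and one VC-like (`VC` or `GC`)
#'   fragment are required: BiFC needs both halves.
#' @param intramolecular `TRUE` when both fragments sit on one construct, in
#'   which case same-monomer fragment pairs are admissible in addition to
#'   cross-monomer pairs.
#' @return An object of class `fusion_experiment`.
#' @export
fusion_experiment <- function(id, tags, intramolecular = FALSE) {
  stopifnot(is.character(id), length(id) == 1L)
  frags <- vapply(tags, function(t) t$fragment, character(1))
  n_vn <- sum(frags == "VN")
  n_vc <- sum(frags %in% c("VC", "GC"))
  if (n_vn != 1L || n_vc != 1L) {
    stop_param("experiment '%s' needs exactly one VN-like and one VC-like fragment", id)
  }
  anchors <- vapply(tags, function(t) t$anchor, character(1))
  if (!all(anchors %in% c("N_term", "C_term", "loop3"))) {
    stop_param("unknown anchor kind in experiment '%s'", id)
  }
  structure(list(id = id, tags = tags, intramolecular = isTRUE(intramolecular)),
            class = "fusion_experiment")
}

#' The five standard intermolecular fusion experiments
#'
#' The four terminal-fusion combinations (both N-termini; VC at an N-terminus
#' with VN at a C-terminus; VN at an N-terminus with VC at a C-terminus; both
#' C-termini) plus the loop-3 insertion experiment (GC inserted in
#' intracellular loop 3 of one construct, VN fused to the C-terminus of the
#' other).
#'
#' @return Named list of `fusion_experiment` objects with ids `nn`,
#'   `vcn_vnc`, `vnn_vcc`, `cc`, `loop3`.
#' @export
trk1_bifc_experiments <- function() {
  list(
    nn = fusion_experiment("nn", list(
      list(construct = 1L, anchor = "N_term", fragment = "VN"),
      list(construct = 2L, anchor = "N_term", fragment = "VC")
    )),
    vcn_vnc = fusion_experiment("vcn_vnc", list(
      list(construct = 1L, anchor = "N_term", fragment = "VC"),
      list(construct = 2L, anchor = "C_term", fragment = "VN")
    )),
    vnn_vcc = fusion_experiment("vnn_vcc", list(
      list(construct = 1L, anchor = "N_term", fragment = "VN"),
      list(construct = 2L, anchor = "C_term", fragment = "VC")
    )),
    cc = fusion_experiment("cc", list(
      list(construct = 1L, anchor = "C_term", fragment = "VN"),
      list(construct = 2L, anchor = "C_term", fragment = "VC")
    )),
    loop3 = fusion_experiment("loop3", list(
      list(construct = 1L, anchor = "loop3", fragment = "GC"),
      list(construct = 2L, anchor = "C_term", fragment = "VN")
    ))
  )
}

#' The intramolecular reporter experiment
#'
#' VN at the N-terminus and VC at the C-terminus of a single construct
#' (the monomer reporter used in the semi-quantitative analysis).
#'
#' @return A `fusion_experiment` with `intramolecular = TRUE`.
#' @export
trk1_intramolecular_experiment <- function() {
  fusion_experiment("intra", list(
    list(construct = 1L, anchor = "N_term", fragment = "VN"),
    list(construct = 1L, anchor = "C_term", fragment = "VC")
  ), intramolecular = TRUE)
}

#' Default declarative steric-block rules
#'
#' Cells where the coarse distance criterion passes but complementation is
#' prevented by clashes seen in atomic-scale models: the DA/AD dimer with
#' both fragments at the N-termini (a steric conflict between the loops
#' connecting MPMs C and D), and tetramer A for VN at an N-terminus combined
#' with VC at a C-terminus (clashes between the reconstituted fluorophores).
#'
#' @return `data.frame` with columns `arrangement`, `experiment`, `reason`.
#' @export
default_block_rules <- function() {
  data.frame(
    arrangement = c("dimer_DA", "tetramer_A"),
    experiment = c("nn", "vnn_vcc"),
    reason = c(
      "steric conflict between the loops connecting MPMs C and D",
      "clash between reconstituted fluorophores in the tetramer"
    ),
    stringsAsFactors = FALSE
  )
}

#' Feasibility-prediction configuration
#'
#' @param fp_diameter Diameter of the reconstituted fluorophore disk (model
#'   units).
#' @param clash_tol_frac Tolerated domain-disk interpenetration of the
#'   fluorophore disk, as a fraction of `fp_diameter`.
#' @param block_rules `data.frame(arrangement, experiment, reason)` of
#'   declarative steric-block rules (see [default_block_rules()]).
#' @return Object of class `feasibility_config`.
#' @export
feasibility_config <- function(fp_diameter = 0.15,
                               clash_tol_frac = 0.05,
                               block_rules = default_block_rules()) {
  check_positive_scalar(fp_diameter, "fp_diameter")
  check_nonneg_scalar(clash_tol_frac, "clash_tol_frac")
  structure(list(fp_diameter = fp_diameter,
                 clash_tol_frac = clash_tol_frac,
                 block_rules = block_rules),
            class = "feasibility_config")
}

# All admissible (VN-monomer, VC-monomer) index pairs.
admissible_pairs <- function(n_monomers, intramolecular) {
  pairs <- expand.grid(p = seq_len(n_monomers), q = seq_len(n_monomers))
  if (!intramolecular) pairs <- pairs[pairs$p != pairs$q, , drop = FALSE]
  pairs
}

#' Predict BiFC feasibility for one arrangement and one experiment
#'
#' Over all admissible fragment-anchor pairs (cross-monomer; same-monomer too
#' for intramolecular experiments), finds the minimum anchor-anchor distance.
#' The verdict is `feasible` when some pair is within
#' `reach(VN anchor) + reach(VC anchor) + fp_diameter` *and* the fluorophore
#' disk admits a placement on the inner half of that pair's anchor-anchor
#' segment that does not interpenetrate any MPM domain disk beyond
#' tolerance; `blocked` when the distance criterion passes but a declarative
#' steric-block rule fires; `infeasible` otherwise.
#'
#' @param arrangement An `arrangement`.
#' @param experiment A `fusion_experiment`.
#' @param config A `feasibility_config`.
#' @return Object of class `feasibility_verdict`: `value`,
#'   `min_pair_distance`, `threshold`, `blocking_reason`.
#' @export
#' @examples
#' arr <- build_arrangement("dimer", "CD")
#' predict_bifc(arr, trk1_bifc_experiments()$cc)
predict_bifc <- function(arrangement, experiment, config = feasibility_config()) {
  stopifnot(inherits(arrangement, "arrangement"),
            inherits(experiment, "fusion_experiment"),
            inherits(config, "feasibility_config"))
  lay <- arrangement$layout
  frags <- vapply(experiment$tags, function(t) t$fragment, character(1))
  tag_vn <- experiment$tags[[which(frags == "VN")]]
  tag_vc <- experiment$tags[[which(frags %in% c("VC", "GC"))]]
  for (tg in list(tag_vn, tag_vc)) {
    if (!tg$anchor %in% names(lay$anchor_offsets)) {
      stop_param("anchor '%s' required by experiment '%s' is missing from the layout",
                 tg$anchor, experiment$id)
    }
  }
  thr <- unname(lay$linker_reach[[tag_vn$anchor]] +
                  lay$linker_reach[[tag_vc$anchor]] +
                  config$fp_diameter)

  n_mono <- length(arrangement$poses)
  pairs <- admissible_pairs(n_mono, experiment$intramolecular)
  if (nrow(pairs) == 0L) {
    return(new_verdict("infeasible", Inf, thr, "no admissible fragment pair"))
  }

  dom <- arrangement_domains(arrangement)
  fp_r <- config$fp_diameter / 2
  clash_tol <- config$clash_tol_frac * config$fp_diameter

  best_all <- Inf
  best_free <- Inf
  for (k in seq_len(nrow(pairs))) {
    a1 <- anchor_position(arrangement, pairs$p[k], tag_vn$anchor)
    a2 <- anchor_position(arrangement, pairs$q[k], tag_vc$anchor)
    d <- sqrt(sum((a1 - a2)^2))
    best_all <- min(best_all, d)
    if (d >= best_free) next
    for (f in .fp_placement_fracs) {
      pos <- a1 + f * (a2 - a1)
      pen <- (lay$domain_radius + fp_r) -
        sqrt((dom$x - pos[1])^2 + (dom$y - pos[2])^2)
      if (max(pen) <= clash_tol) {
        best_free <- d
        break
      }
    }
  }

  if (best_free <= thr) {
    br <- config$block_rules
    hit <- which((br$arrangement == arrangement$id | br$arrangement == "*") &
                   (br$experiment == experiment$id | br$experiment == "*"))
    if (length(hit) > 0L) {
      return(new_verdict("blocked", best_all, thr, br$reason[hit[1]]))
    }
    return(new_verdict("feasible", best_all, thr, NA_character_))
  }
  reason <- if (best_all <= thr) "fluorophore placement clashes with domain disks"
            else "anchors beyond combined tether reach"
  new_verdict("infeasible", best_all, thr, reason)
}

new_verdict <- function(value, dist, thr, reason) {
  structure(list(value = value, min_pair_distance = dist,
                 threshold = thr, blocking_reason = reason),
            class = "feasibility_verdict")
}

#' @export
print.feasibility_verdict <- function(x, ...) {
  cat(sprintf("<feasibility_verdict> %s (min distance %.3f, threshold %.3f)\n",
              x$value, x$min_pair_distance, x$threshold))
  if (!is.na(x$blocking_reason)) cat("  reason:", x$blocking_reason, "\n")
  invisible(x)
}

#' Compute the full arrangement x experiment feasibility table
#'
#' @param arrangements Named list of `arrangement` objects (default: the nine
#'   standard symmetric arrangements).
#' @param experiments Named list of `fusion_experiment` objects (default: the
#'   five standard intermolecular experiments).
#' @param config A `feasibility_config`.
#' @return Object of class `feasibility_table`: a long `data.frame` in
#'   `$entries` (`arrangement`, `experiment`, `verdict`, `min_distance`,
#'   `threshold`, `reason`) with attribute `provenance = "computed"`.
#' @export
#' @examples
#' tab <- compute_feasibility_table()
#' feasibility_matrix(tab)
compute_feasibility_table <- function(arrangements = standard_arrangements(),
                                      experiments = trk1_bifc_experiments(),
                                      config = feasibility_config()) {
  if (length(arrangements) == 0L || length(experiments) == 0L) {
    stop_param("`arrangements` and `experiments` must be non-empty")
  }
  rows <- list()
  for (arr in arrangements) {
    for (ex in experiments) {
      v <- predict_bifc(arr, ex, config)
      rows[[length(rows) + 1L]] <- data.frame(
        arrangement = arr$id, experiment = ex$id, verdict = v$value,
        min_distance = v$min_pair_distance, threshold = v$threshold,
        reason = v$blocking_reason, stringsAsFactors = FALSE
      )
    }
  }
  new_feasibility_table(do.call(rbind, rows), provenance = "computed")
}

#' Build a feasibility table from a verdict data frame
#'
#' @param entries `data.frame` with columns `arrangement`, `experiment`,
#'   `verdict` (values `feasible`, `blocked`, `infeasible`); optional
#'   numeric columns are kept.
#' @param provenance Provenance string.
#' @return A `feasibility_table`.
#' @export
as_feasibility_table <- function(entries, provenance = "user") {
  if (!all(entries$verdict %in% c("feasible", "blocked", "infeasible"))) {
    stop_param("verdicts must be feasible/blocked/infeasible")
  }
  for (col in c("min_distance", "threshold", "reason")) {
    if (!col %in% names(entries)) entries[[col]] <- NA
  }
  new_feasibility_table(entries, provenance)
}

new_feasibility_table <- function(entries, provenance) {
  stopifnot(all(c("arrangement", "experiment", "verdict") %in% names(entries)))
  structure(list(entries = entries, provenance = provenance),
            class = "feasibility_table")
}

#' @export
print.feasibility_table <- function(x, ...) {
  cat("<feasibility_table>", nrow(x$entries), "cells, provenance:",
      x$provenance, "\n")
  print(feasibility_matrix(x))
  invisible(x)
}

#' Verdict matrix of a feasibility table
#'
#' @param table A `feasibility_table`.
#' @return Character matrix, rows = arrangements, columns = experiments.
#' @export
feasibility_matrix <- function(table) {
  stopifnot(inherits(table, "feasibility_table"))
  e <- table$entries
  arrs <- unique(e$arrangement)
  exps <- unique(e$experiment)
  m <- matrix(NA_character_, length(arrs), length(exps),
              dimnames = list(arrs, exps))
  m[cbind(match(e$arrangement, arrs), match(e$experiment, exps))] <- e$verdict
  m
}

#' Reference feasibility table from atomic-scale structural modelling
#'
#' The tri-state verdicts (feasible / blocked / infeasible) for the nine
#' symmetric arrangements and five standard fusion experiments, as
#' established by the published atomic-scale structural analysis of the
#' transporter that this coarse-grained geometry reproduces.  The two
#' `blocked` cells record clash-based exclusions where the distance
#' criterion alone would allow complementation.
#'
#' @return A `feasibility_table` with `provenance = "reported"`.
#' @export
reported_feasibility_table <- function() {
  exps <- c("nn", "vcn_vnc", "vnn_vcc", "cc", "loop3")
  verdicts <- rbind(
    monomer    = c("infeasible", "infeasible", "infeasible", "infeasible", "infeasible"),
    dimer_AB   = c("feasible",   "infeasible", "infeasible", "infeasible", "infeasible"),
    dimer_BC   = c("feasible",   "infeasible", "infeasible", "infeasible", "feasible"),
    dimer_CD   = c("infeasible", "feasible",   "feasible",   "feasible",   "feasible"),
    dimer_DA   = c("blocked",    "feasible",   "feasible",   "feasible",   "infeasible"),
    tetramer_A = c("feasible",   "feasible",   "blocked",    "infeasible", "feasible"),
    tetramer_B = c("feasible",   "feasible",   "feasible",   "infeasible", "feasible"),
    tetramer_C = c("feasible",   "feasible",   "feasible",   "feasible",   "infeasible"),
    tetramer_D = c("infeasible", "feasible",   "feasible",   "feasible",   "infeasible")
  )
  colnames(verdicts) <- exps
  entries <- data.frame(
    arrangement = rep(rownames(verdicts), each = length(exps)),
    experiment = rep(exps, times = nrow(verdicts)),
    verdict = as.vector(t(verdicts)),
    min_distance = NA_real_, threshold = NA_real_, reason = NA_character_,
    stringsAsFactors = FALSE
  )
  new_feasibility_table(entries, provenance = "reported")
}

#' Export a feasibility table
#'
#' @param table A `feasibility_table`.
#' @param path Output file path.
#' @param format `"tsv"` (matrix layout: rows = arrangements, columns =
#'   experiments) or `"json"` (long entries plus provenance).
#' @return `path`, invisibly.
#' @export
write_feasibility_table <- function(table, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    m <- feasibility_matrix(table)
    df <- data.frame(arrangement = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(provenance = table$provenance, entries = table$entries),
      path, dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null"
    )
  }
  invisible(path)
}

#' Read a feasibility table written as TSV
#'
#' @param path TSV file as written by [write_feasibility_table()].
#' @param provenance Provenance string to attach.
#' @return A `feasibility_table`.
#' @export
read_feasibility_table <- function(path, provenance = "file") {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  exps <- setdiff(names(df), "arrangement")
  entries <- data.frame(
    arrangement = rep(df$arrangement, each = length(exps)),
    experiment = rep(exps, times = nrow(df)),
    verdict = as.vector(t(as.matrix(df[, exps]))),
    min_distance = NA_real_, threshold = NA_real_, reason = NA_character_,
    stringsAsFactors = FALSE
  )
  new_feasibility_table(entries, provenance = provenance)
}
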