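# Staged constraint-elimination: intersect a BiFC feasibility table with
# observed outcomes to find the oligomer arrangements consistent with the
# data.  Two distinct elimination semantics are applied in order:
#   stage 1 (false-positive rejection): an arrangement predicted `feasible`
#     for an experiment in which BiFC was *not* observed is excluded —
#     it would have produced a signal that never appeared.  `blocked`
#     verdicts do not eliminate: the prediction itself says the signal was
#     not expected.
#   stage 2 (positive-explanation requirement): among the survivors, keep
#     only arrangements predicted `feasible` for every discriminator
#     experiment in which BiFC *was* observed.  Because monomers coexist
#     with multimers in the membrane, a multimer cannot be rejected merely
#     for failing to predict a terminal-fusion positive (a coexisting
#     species may explain it); the discriminator set defaults to the loop-3
#     experiment alone, whose design restricts which arrangements can
#     explain its signal.  The monomer is exempt from stage 2 and reported
#     as a coexisting species.

#' Construct a BiFC observation table
#'
#' @param experiment Character vector of experiment ids.
#' @param observed Character vector, each `"bifc_seen"` or `"no_bifc"`.
#' @return `data.frame` with columns `experiment`, `observed`.
#' @export
#' @examples
#' bifc_observations(c("nn", "cc"), c("no_bifc", "bifc_seen"))
bifc_observations <- function(experiment, observed) {
  stopifnot(length(experiment) == length(observed))
  if (!all(observed %in% c("bifc_seen", "no_bifc"))) {
    stop_param("`observed` values must be 'bifc_seen' or 'no_bifc'")
  }
  data.frame(experiment = as.character(experiment), observed = observed,
             stringsAsFactors = FALSE)
}

#' The published BiFC outcomes of the terminal-fusion experiments
#'
#' No complementation when both fragments were fused to N-termini; clear
#' complementation for the other three terminal combinations.
#'
#' @return Observation `data.frame` (see [bifc_observations()]).
#' @export
trk1_terminal_observations <- function() {
  bifc_observations(
    c("nn", "vcn_vnc", "vnn_vcc", "cc"),
    c("no_bifc", "bifc_seen", "bifc_seen", "bifc_seen")
  )
}

#' The published loop-3 discriminator observation
#'
#' Complementation was observed with the GC fragment inserted in
#' intracellular loop 3 combined with VN at a C-terminus.
#'
#' @return Observation `data.frame`.
#' @export
trk1_discriminator_observations <- function() {
  bifc_observations("loop3", "bifc_seen")
}

check_observations <- function(table, observations) {
  exps <- unique(table$entries$experiment)
  bad <- setdiff(observations$experiment, exps)
  if (length(bad) > 0L) {
    stop_param("observation refers to unknown experiment(s): %s",
               paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

verdict_of <- function(table, arrangement, experiment) {
  e <- table$entries
  v <- e$verdict[e$arrangement == arrangement & e$experiment == experiment]
  if (length(v) != 1L) {
    stop_param("table has no unique entry for (%s, %s)", arrangement, experiment)
  }
  v
}

new_consistency_result <- function(candidates, coexisting, eliminated, rule_trace) {
  structure(list(candidates = candidates, coexisting = coexisting,
                 eliminated = eliminated, rule_trace = rule_trace),
            class = "consistency_result")
}

#' @export
print.consistency_result <- function(x, ...) {
  cat("<consistency_result>\n")
  cat("  candidates:", if (length(x$candidates)) paste(x$candidates, collapse = ", ") else "(none)", "\n")
  if (length(x$coexisting)) cat("  coexisting:", paste(x$coexisting, collapse = ", "), "\n")
  if (nrow(x$eliminated)) {
    cat("  eliminated:\n")
    for (i in seq_len(nrow(x$eliminated))) {
      cat(sprintf("    %-12s stage %d (%s)\n", x$eliminated$arrangement[i],
                  x$eliminated$stage[i], x$eliminated$experiment[i]))
    }
  }
  invisible(x)
}

#' Stage 1: eliminate arrangements contradicted by absent BiFC
#'
#' Removes every arrangement whose verdict is `feasible` for an experiment
#' in which no BiFC was observed (a predicted signal that failed to appear).
#' `blocked` verdicts do not eliminate; positive observations are ignored at
#' this stage.
#'
#' @param table A `feasibility_table`.
#' @param observations Observation `data.frame` ([bifc_observations()]).
#' @return A `consistency_result`.
#' @export
#' @examples
#' eliminate_false_positives(reported_feasibility_table(),
#'                           trk1_terminal_observations())
eliminate_false_positives <- function(table, observations) {
  stopifnot(inherits(table, "feasibility_table"))
  check_observations(table, observations)
  arrs <- unique(table$entries$arrangement)
  neg <- observations[observations$observed == "no_bifc", , drop = FALSE]
  elim <- data.frame(arrangement = character(0), stage = integer(0),
                     experiment = character(0), rule = character(0),
                     stringsAsFactors = FALSE)
  for (a in arrs) {
    for (ex in neg$experiment) {
      if (verdict_of(table, a, ex) == "feasible") {
        elim <- rbind(elim, data.frame(
          arrangement = a, stage = 1L, experiment = ex,
          rule = "predicted feasible but BiFC not observed",
          stringsAsFactors = FALSE
        ))
        break
      }
    }
  }
  surv <- setdiff(arrs, elim$arrangement)
  coex <- intersect(surv, "monomer")
  trace <- data.frame(
    stage = 1L, rule = "false-positive rejection",
    experiments = paste(neg$experiment, collapse = ","),
    eliminated = paste(elim$arrangement, collapse = ","),
    stringsAsFactors = FALSE
  )
  new_consistency_result(setdiff(surv, coex), coex, elim, trace)
}

#' Stage 2: require candidates to explain observed BiFC
#'
#' Retains only candidates whose verdict is `feasible` for every positive
#' discriminator observation.  The monomer is exempt (it is reported as a
#' coexisting species, since single-molecule counting shows monomers and
#' multimers coexist and this logic cannot exclude them).
#'
#' @param candidates Character vector of candidate arrangement ids.
#' @param table A `feasibility_table`.
#' @param positive_observations Observation `data.frame`; rows with
#'   `observed == "bifc_seen"` act as discriminators.
#' @return A `consistency_result` over `candidates`.
#' @export
require_explanation <- function(candidates, table, positive_observations) {
  stopifnot(inherits(table, "feasibility_table"))
  check_observations(table, positive_observations)
  bad <- setdiff(candidates, unique(table$entries$arrangement))
  if (length(bad) > 0L) {
    stop_param("candidate(s) not in table: %s", paste(bad, collapse = ", "))
  }
  pos <- positive_observations[positive_observations$observed == "bifc_seen", , drop = FALSE]
  coex <- intersect(candidates, "monomer")
  elig <- setdiff(candidates, coex)
  elim <- data.frame(arrangement = character(0), stage = integer(0),
                     experiment = character(0), rule = character(0),
                     stringsAsFactors = FALSE)
  for (a in elig) {
    for (ex in pos$experiment) {
      if (verdict_of(table, a, ex) != "feasible") {
        elim <- rbind(elim, data.frame(
          arrangement = a, stage = 2L, experiment = ex,
          rule = "cannot explain observed BiFC",
          stringsAsFactors = FALSE
        ))
        break
      }
    }
  }
  trace <- data.frame(
    stage = 2L, rule = "positive-explanation requirement",
    experiments = paste(pos$experiment, collapse = ","),
    eliminated = paste(elim$arrangement, collapse = ","),
    stringsAsFactors = FALSE
  )
  new_consistency_result(setdiff(elig, elim$arrangement), coex, elim, trace)
}

#' Run the staged oligomer-arrangement inference
#'
#' Stage 1 ([eliminate_false_positives()]) on the terminal observations,
#' then stage 2 ([require_explanation()]) on the discriminator
#' observations.  The monomer arrangement, when present in the table, is
#' always reported alongside the multimer candidates as a coexisting
#' species.
#'
#' @param table A `feasibility_table` (default: the reference table).
#' @param terminal_observations Stage-1 observations (default: the published
#'   terminal-fusion outcomes).
#' @param discriminator_observations Stage-2 observations (default: the
#'   published loop-3 positive).
#' @return A `consistency_result` with a two-stage `rule_trace`.
#' @export
#' @examples
#' run_inference()  # leaves only the CD/DC dimer (plus coexisting monomers)
run_inference <- function(table = reported_feasibility_table(),
                          terminal_observations = trk1_terminal_observations(),
                          discriminator_observations = trk1_discriminator_observations()) {
  s1 <- eliminate_false_positives(table, terminal_observations)
  s2 <- require_explanation(c(s1$candidates, s1$coexisting), table,
                            discriminator_observations)
  new_consistency_result(
    candidates = s2$candidates,
    coexisting = s2$coexisting,
    eliminated = rbind(s1$eliminated, s2$eliminated),
    rule_trace = rbind(s1$rule_trace, s2$rule_trace)
  )
}

#' Export a consistency result as JSON
#'
#' @param result A `consistency_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_consistency_result <- function(result, path) {
  stopifnot(inherits(result, "consistency_result"))
  jsonlite::write_json(
    list(candidates = result$candidates, coexisting = result$coexisting,
         eliminated = result$eliminated, rule_trace = result$rule_trace),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}
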