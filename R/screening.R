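## Two-stage environmental-variable screening:
##   stage 1 — iteratively refit the model and drop every variable whose
##             percent contribution is (printed-)zero, until stable;
##   stage 2 — Pearson correlation filter at presence points: among highly
##             correlated pairs keep the higher-contribution member.

#' Stage 1: iterative elimination of zero-contribution variables
#'
#' Fits the maximum-entropy model on the current variable set, computes
#' percent contributions, drops all variables whose contribution falls
#' below `epsilon_zero` (percentage points), and repeats until no variable
#' is dropped or one variable remains. Every round is reported.
#'
#' @param stack A [grid_stack()].
#' @param occ Presence points as in [maxent()].
#' @param config A [maxent_config()].
#' @param epsilon_zero Contribution (in percentage points) below which a
#'   variable counts as zero (default 1e-6).
#' @return A list with `rounds` (one data frame per round: variable,
#'   contribution, dropped), `final_variables`, and `contributions` (from
#'   the final round).
#' @export
drop_zero_contribution <- function(stack, occ, config = maxent_config(),
                                   epsilon_zero = 1e-6) {
  vars <- names(stack$layers)
  if (length(vars) < 2) stop("drop_zero_contribution: need >= 2 variables")
  rounds <- list()
  repeat {
    model <- maxent(subset_stack(stack, vars), occ, config)
    pc <- percent_contribution(model)
    if (length(rounds) == 0 && sum(pc) <= 0)
      stop("drop_zero_contribution: all variables have zero contribution (degenerate model)")
    drop <- names(pc)[pc < epsilon_zero]
    rounds[[length(rounds) + 1L]] <- data.frame(
      variable = names(pc), contribution = as.numeric(pc),
      dropped = names(pc) %in% drop, stringsAsFactors = FALSE)
    if (length(drop) == 0 || length(vars) - length(drop) <= 1) {
      if (length(vars) - length(drop) >= 1 && length(drop) > 0)
        vars <- setdiff(vars, drop)
      break
    }
    vars <- setdiff(vars, drop)
  }
  final_pc <- rounds[[length(rounds)]]
  final_pc <- final_pc[!final_pc$dropped, , drop = FALSE]
  list(rounds = rounds, final_variables = vars,
       contributions = stats::setNames(final_pc$contribution,
                                       final_pc$variable))
}

#' Stage 2: pairwise correlation filter
#'
#' Computes Pearson correlations between variables at presence points,
#' processes pairs in decreasing absolute correlation, and for every pair
#' exceeding `threshold` whose members both still survive drops the member
#' with the smaller contribution (ties drop the later variable in input
#' order). Variables with zero variance at the presence points are dropped
#' first with reason `"degenerate"`. The surviving set contains no pair
#' with `|r| > threshold`.
#'
#' @param values Data frame or matrix of variable values at presence
#'   points (one column per variable), e.g. from [extract_values()].
#' @param contributions Named percent-contribution vector covering every
#'   variable in `values`.
#' @param threshold Correlation threshold (default 0.8).
#' @return A list with `correlation_matrix`, `decisions` (data frame:
#'   var_a, var_b, r, dropped, reason), and `final_variables`.
#' @export
correlation_filter <- function(values, contributions, threshold = 0.8) {
  values <- as.matrix(values)
  vars <- colnames(values)
  stopifnot(all(vars %in% names(contributions)))
  decisions <- data.frame(var_a = character(), var_b = character(),
                          r = numeric(), dropped = character(),
                          reason = character(), stringsAsFactors = FALSE)
  sds <- apply(values, 2, stats::sd)
  degenerate <- vars[sds < 1e-12 | is.na(sds)]
  for (v in degenerate)
    decisions[nrow(decisions) + 1L, ] <-
      list(v, NA_character_, NA_real_, v, "degenerate")
  alive <- setdiff(vars, degenerate)
  R <- if (length(alive) >= 2) stats::cor(values[, alive, drop = FALSE])
       else matrix(1, length(alive), length(alive),
                   dimnames = list(alive, alive))
  if (length(alive) >= 2) {
    pairs <- which(upper.tri(R), arr.ind = TRUE)
    ord <- order(-abs(R[pairs]), pairs[, 1], pairs[, 2])
    pairs <- pairs[ord, , drop = FALSE]
    surviving <- alive
    for (k in seq_len(nrow(pairs))) {
      a <- alive[pairs[k, 1]]; b <- alive[pairs[k, 2]]
      r <- R[pairs[k, 1], pairs[k, 2]]
      if (abs(r) <= threshold) break  # sorted: nothing further exceeds
      if (!(a %in% surviving) || !(b %in% surviving)) next
      ca <- contributions[[a]]; cb <- contributions[[b]]
      loser <- if (ca > cb) b
               else if (cb > ca) a
               else vars[max(match(a, vars), match(b, vars))]  # tie: later
      surviving <- setdiff(surviving, loser)
      decisions[nrow(decisions) + 1L, ] <-
        list(a, b, r, loser, "correlated")
    }
    alive <- surviving
  }
  list(correlation_matrix = R, decisions = decisions,
       final_variables = vars[vars %in% alive])
}

#' Two-stage environmental-variable screening
#'
#' Runs [drop_zero_contribution()] on the stack, extracts the surviving
#' variables' values at the presence points, and applies
#' [correlation_filter()]. The returned report carries every round and
#' decision so each dropped variable is accounted for exactly once.
#'
#' @param stack A [grid_stack()] of candidate variables.
#' @param occ An `occurrence_set` of presences.
#' @param config A [maxent_config()].
#' @param threshold Correlation threshold for stage 2 (default 0.8).
#' @param epsilon_zero Zero-contribution cut for stage 1.
#' @return An object of class `screening_report`: `rounds`,
#'   `correlation_matrix`, `decisions`, `contributions`,
#'   `final_variables`.
#' @export
screen_variables <- function(stack, occ, config = maxent_config(),
                             threshold = 0.8, epsilon_zero = 1e-6) {
  s1 <- drop_zero_contribution(stack, occ, config, epsilon_zero)
  ex <- extract_values(subset_stack(stack, s1$final_variables), occ)
  vals <- ex$values[, s1$final_variables, drop = FALSE]
  s2 <- correlation_filter(vals, s1$contributions, threshold)
  structure(list(rounds = s1$rounds,
                 correlation_matrix = s2$correlation_matrix,
                 decisions = s2$decisions,
                 contributions = s1$contributions,
                 threshold = threshold,
                 final_variables = s2$final_variables),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  n0 <- nrow(x$rounds[[1]])
  cat(sprintf("<screening_report> %d -> %d variables (%d zero-contribution round(s), threshold |r| > %.2f)\n",
              n0, length(x$final_variables), length(x$rounds), x$threshold))
  cat(" final:", paste(x$final_variables, collapse = ", "), "\n")
  invisible(x)
}

#' Serialise a screening report
#'
#' Writes per-round contributions as CSV and the correlation decisions as
#' a JSON log.
#'
#' @param report A `screening_report`.
#' @param csv_path,json_path Output paths.
#' @return Invisibly, `report`.
#' @export
write_screening_report <- function(report, csv_path, json_path) {
  rounds <- do.call(rbind, lapply(seq_along(report$rounds), function(i)
    cbind(round = i, report$rounds[[i]])))
  utils::write.csv(rounds, csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(threshold = report$threshold,
         decisions = report$decisions,
         final_variables = report$final_variables),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
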