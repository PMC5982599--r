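## Greedy threshold-rule descriptor selection: each rule defines a benign
## interval on one descriptor; lesions falling outside any selected
## rule's interval are called malignant. Rules are ranked by how many
## melanomas they flag and accumulated greedily while each addition
## catches at least one new melanoma.

#' Interval rule on one descriptor
#'
#' The closed interval `[lower, upper]` is the benign zone; values
#' strictly outside it flag the lesion as malignant.
#'
#' @param descriptor descriptor id string, see [descriptor_ids()].
#' @param upper,lower interval bounds (`lower < upper`).
#' @return A `threshold_rule` object.
#' @export
threshold_rule <- function(descriptor, upper, lower) {
  stopifnot(is.character(descriptor), length(descriptor) == 1)
  parse_descriptor_id(descriptor)   # validates the id format
  if (!(lower < upper)) stop("threshold_rule requires lower < upper")
  structure(list(descriptor = descriptor, upper = as.numeric(upper),
                 lower = as.numeric(lower)), class = "threshold_rule")
}

#' @export
print.threshold_rule <- function(x, ...) {
  cat(sprintf("<threshold_rule %s: benign in [%g, %g]>\n",
              x$descriptor, x$lower, x$upper))
  invisible(x)
}

#' Default rule set
#'
#' The eight descriptor interval rules shipped as defaults, in the order
#' of their experimentally set thresholds: minimum of the minus-skin
#' reflectance at 414 nm, absorbance SD and energy at 477 nm, reflectance
#' energy at 524 nm, reflectance skewness at 671 nm, reflectance mean at
#' 995 nm, minus-skin absorbance SD at 1214 nm, and minimum absorbance at
#' 1613 nm.
#'
#' @return list of [threshold_rule()]s.
#' @export
default_rules <- function() {
  list(
    threshold_rule("VISNIR.414.R_minus_skin.min", upper = 0.8, lower = -0.33),
    threshold_rule("VISNIR.477.A.std", upper = 0.082, lower = 0.039),
    threshold_rule("VISNIR.477.A.energy", upper = 0.125, lower = 0.046),
    threshold_rule("VISNIR.524.R.energy", upper = 0.28, lower = 0.03),
    threshold_rule("VISNIR.671.R.mu3", upper = 1.8e-3, lower = -2),
    threshold_rule("VISNIR.995.R.mean", upper = 0.55, lower = 0.4),
    threshold_rule("EXNIR.1214.A_minus_skin.std", upper = 0.082, lower = 0.04),
    threshold_rule("EXNIR.1613.A.min", upper = 1.95, lower = 1.18)
  )
}

#' Does a descriptor value flag malignancy under a rule?
#'
#' @param value numeric (vectorized).
#' @param rule a [threshold_rule()].
#' @return logical: TRUE iff `value > upper` or `value < lower` (strict;
#'   values exactly on a bound are benign).
#' @export
flag_malignant <- function(value, rule) {
  value > rule$upper | value < rule$lower
}

rule_flags <- function(table, rule) {
  if (!rule$descriptor %in% names(table))
    stop("descriptor not in table: ", rule$descriptor)
  flag_malignant(table[[rule$descriptor]], rule)
}

#' Rank rules by melanomas caught
#'
#' Orders rules by decreasing count of true melanomas they flag; ties
#' keep the incoming order (which follows the table's column order for
#' rule sets built in column order).
#'
#' @param table descriptor table with a `class` column.
#' @param rules list of [threshold_rule()]s.
#' @return the reordered rule list, with a `"melanomas_caught"` attribute.
#' @export
rank_rules <- function(table, rules) {
  mel <- table$class == "melanoma"
  counts <- vapply(rules, function(r) sum(rule_flags(table, r) & mel),
                   numeric(1))
  ord <- order(-counts)  # stable: ties keep input order
  structure(rules[ord], melanomas_caught = counts[ord])
}

#' Greedy accumulation of ranked rules
#'
#' Starting from the top-ranked rule, each candidate is accepted iff the
#' union of flagged melanomas grows by at least one; otherwise it is
#' discarded as redundant. The whole ranked list is scanned once.
#' Cumulative sensitivity (flagged melanomas / total melanomas) is
#' recorded after each acceptance and is strictly increasing.
#'
#' @param table descriptor table with a `class` column containing at
#'   least one melanoma.
#' @param ranked_rules rules in rank order (see [rank_rules()]).
#' @return A `selection_result`: list with `selected` (accepted rules),
#'   `cumulative_sensitivity` (fraction per accepted step), `discarded`
#'   (rules with `reason`) and `n_melanomas`.
#' @export
greedy_select <- function(table, ranked_rules) {
  mel_idx <- which(table$class == "melanoma")
  if (length(mel_idx) == 0) stop("no melanomas in table")
  caught <- integer(0)
  selected <- list(); cum_sens <- numeric(0); discarded <- list()
  for (r in ranked_rules) {
    flagged <- intersect(which(rule_flags(table, r)), mel_idx)
    new_caught <- union(caught, flagged)
    if (length(new_caught) > length(caught)) {
      caught <- new_caught
      selected[[length(selected) + 1]] <- r
      cum_sens <- c(cum_sens, length(caught) / length(mel_idx))
    } else {
      discarded[[length(discarded) + 1]] <-
        list(rule = r, reason = "redundant: no new melanoma flagged")
    }
  }
  structure(list(selected = selected, cumulative_sensitivity = cum_sens,
                 discarded = discarded, n_melanomas = length(mel_idx)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result: %d rules accepted, %d discarded>\n",
              length(x$selected), length(x$discarded)))
  for (i in seq_along(x$selected))
    cat(sprintf("  %d. %-34s cum. sensitivity %.1f%%\n", i,
                x$selected[[i]]$descriptor,
                100 * x$cumulative_sensitivity[i]))
  invisible(x)
}

#' Classify lesions by a rule set
#'
#' A lesion is malignant iff at least one rule flags it.
#'
#' @param table descriptor table (rows = lesions).
#' @param rules non-empty list of [threshold_rule()]s.
#' @return character vector `"malignant"` / `"benign"` per row.
#' @export
classify_by_rules <- function(table, rules) {
  if (length(rules) == 0) stop("no rules supplied")
  flags <- Reduce(`|`, lapply(rules, function(r) rule_flags(table, r)))
  ifelse(flags, "malignant", "benign")
}

#' Fit interval thresholds to a cohort (non-default extension)
#'
#' The shipped defaults carry experimentally set thresholds; this helper
#' instead derives, per descriptor, the benign interval from the nevus
#' value distribution: the widest symmetric quantile interval
#' `[q_alpha, q_{1-alpha}]` over a grid of `alpha` values that flags at
#' most `max_nevi_flagged` nevi, preferring the interval catching the
#' most melanomas. This is a pragmatic calibration aid, not part of the
#' reference procedure.
#'
#' @param table descriptor table with a `class` column.
#' @param descriptors descriptor ids to fit rules for.
#' @param max_nevi_flagged tolerated false positives per rule.
#' @param alphas candidate tail probabilities.
#' @return list of [threshold_rule()]s.
#' @export
fit_rules <- function(table, descriptors, max_nevi_flagged = 2,
                      alphas = c(0.25, 0.15, 0.1, 0.05, 0.025, 0)) {
  nev <- table$class == "nevus"
  mel <- table$class == "melanoma"
  lapply(descriptors, function(d) {
    v <- table[[d]]
    if (is.null(v)) stop("descriptor not in table: ", d)
    best <- NULL; best_caught <- -1
    for (a in alphas) {
      q <- stats::quantile(v[nev], c(a, 1 - a), names = FALSE, type = 7)
      if (q[1] >= q[2]) next
      fp <- sum(v[nev] > q[2] | v[nev] < q[1])
      if (fp > max_nevi_flagged) next
      caught <- sum(v[mel] > q[2] | v[mel] < q[1])
      if (caught > best_caught) {
        best_caught <- caught
        best <- threshold_rule(d, upper = q[2], lower = q[1])
      }
    }
    if (is.null(best))
      best <- threshold_rule(d, upper = max(v[nev]), lower = min(v[nev]) -
                               1e-12 * max(1, abs(min(v[nev]))))
    best
  })
}

#' Serialize / read rule sets as JSON
#'
#' @param rules list of [threshold_rule()]s.
#' @param path JSON file path.
#' @return `read_rules()` returns a list of [threshold_rule()]s.
#' @export
write_rules <- function(rules, path) {
  jsonlite::write_json(
    lapply(rules, function(r) list(descriptor = r$descriptor,
                                   upper = r$upper, lower = r$lower)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, function(r) threshold_rule(r$descriptor, r$upper, r$lower))
}
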