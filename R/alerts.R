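## Rule-based alerts over a results bundle. Each rule points at a
## metric inside the bundle by a dotted path and fires on a strict
## comparison, so boundary values never trigger. The two shipped
## rules flag an elevated uncalled-base (N) frequency and a
## forward/reverse strand imbalance.

#' Construct an alert rule
#'
#' @param id short rule identifier
#' @param metric dotted path into a results bundle, e.g.
#'   `"composition.n_base_fraction"`
#' @param comparator `"gt"` or `"lt"`; strict in both cases
#' @param threshold finite numeric threshold
#' @param message message template; `{observed}` and `{threshold}`
#'   are substituted
#' @return an `alert_rule`
#' @export
alert_rule <- function(id, metric, comparator = c("gt", "lt"), threshold,
                       message = "{id}: observed {observed} vs threshold {threshold}") {
  comparator <- match.arg(comparator)
  stopifnot(is_scalar_number(threshold))
  structure(list(id = id, metric = metric, comparator = comparator,
                 threshold = threshold, message = message),
            class = "alert_rule")
}

#' The default alert rule set
#'
#' Fires when the overall frequency of uncalled bases exceeds 0.5%,
#' or when more than 55% of reads map to one strand. Both thresholds
#' are strict: exactly 0.5% or 55% does not fire.
#' @return list of `alert_rule`s
#' @export
default_alert_rules <- function() {
  list(
    alert_rule(
      "n_frequency", "composition.n_base_fraction", "gt", 0.005,
      "uncalled-base (N) frequency {observed} exceeds {threshold}"
    ),
    alert_rule(
      "strand_bias", "mapping.strand.max_fraction", "gt", 0.55,
      "strand imbalance: {observed} of reads map to one strand (limit {threshold})"
    )
  )
}

#' Read additional alert rules from a JSON config
#'
#' The config is a JSON array of objects with fields id, metric,
#' comparator, threshold, and optional message.
#'
#' @param path JSON file path
#' @return list of `alert_rule`s
#' @export
alert_rules_from_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(raw, function(r) {
    alert_rule(r$id, r$metric, r$comparator, r$threshold,
               if (is.null(r$message)) {
                 "{id}: observed {observed} vs threshold {threshold}"
               } else {
                 r$message
               })
  })
}

resolve_metric <- function(results, path) {
  cur <- results
  for (part in strsplit(path, ".", fixed = TRUE)[[1]]) {
    if (!is.list(cur) || is.null(cur[[part]])) {
      bd_stop("UnresolvableMetric",
              sprintf("metric path '%s' not found in results bundle", path))
    }
    cur <- cur[[part]]
  }
  if (!is_scalar_number(cur)) {
    bd_stop("UnresolvableMetric",
            sprintf("metric path '%s' is not a finite scalar", path))
  }
  cur
}

#' Evaluate alert rules against a results bundle
#'
#' @param results a `results_bundle` (or a plain nested list exposing
#'   the rule metric paths)
#' @param rules list of [alert_rule()]s; defaults to
#'   [default_alert_rules()]
#' @return list of alerts, each a list(rule_id, observed, threshold,
#'   comparator, message); empty when no rule fires
#' @export
evaluate_alerts <- function(results, rules = default_alert_rules()) {
  alerts <- list()
  for (rule in rules) {
    observed <- resolve_metric(results, rule$metric)
    fired <- switch(rule$comparator,
                    gt = observed > rule$threshold,
                    lt = observed < rule$threshold)
    if (isTRUE(fired)) {
      msg <- rule$message
      msg <- gsub("{id}", rule$id, msg, fixed = TRUE)
      msg <- gsub("{observed}", format(signif(observed, 4)), msg, fixed = TRUE)
      msg <- gsub("{threshold}", format(rule$threshold), msg, fixed = TRUE)
      alerts[[length(alerts) + 1L]] <- list(
        rule_id = rule$id, observed = observed, threshold = rule$threshold,
        comparator = rule$comparator, message = msg
      )
    }
  }
  alerts
}
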