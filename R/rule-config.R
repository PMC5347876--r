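# Editable rule configuration.
#
# The scheduling rule table is deliberately data, not code: clinics with
# different monitoring policies (or future guidelines) can reuse the
# classifier by adjusting thresholds and intervals.

RULE_IDS <- c("diagnosis", "aids", "art_start", "art_switch",
              "cd4_le350_drop", "cd4_le350_stable", "cd4_351_499",
              "cd4_ge500_drop_ge100", "cd4_ge500_high_vl", "cd4_ge500_low_vl",
              "vl_gt200", "vl_low_not_blip", "vl_low_blip",
              "vl_supp_cd4_le200", "vl_supp_cd4_gt200")

#' Rule configuration for the expected-interval engine
#'
#' Returns the default rule table mapping episode clinical state to the number
#' of months within which the next care episode is expected, with every
#' threshold and interval overridable. The defaults encode standard UK
#' monitoring practice at the time the measure was developed: recent
#' diagnosis, an AIDS event, starting ART or switching regimen all demand
#' review within 2 months; untreated patients are recalled every 2-6 months
#' mainly by CD4 count; treated patients every 2-6 months mainly by viral
#' load; 6 months is the maximum routine gap.
#'
#' @param intervals Named list overriding per-rule intervals (months). Rule
#'   identifiers: `diagnosis`, `aids`, `art_start`, `art_switch`,
#'   `cd4_le350_drop`, `cd4_le350_stable`, `cd4_351_499`,
#'   `cd4_ge500_drop_ge100`, `cd4_ge500_high_vl`, `cd4_ge500_low_vl`,
#'   `vl_gt200`, `vl_low_not_blip`, `vl_low_blip`, `vl_supp_cd4_le200`,
#'   `vl_supp_cd4_gt200`.
#' @param routine_months Maximum routine recall interval; supplies the default
#'   interval for the two stable-patient rules (`cd4_ge500_low_vl`,
#'   `vl_supp_cd4_gt200`). Default 6.
#' @param cd4_low,cd4_high CD4 thresholds (cells/uL) splitting untreated
#'   patients at <=350 / 351-499 / >=500. Defaults 350 and 500.
#' @param cd4_drop_high CD4 drop (cells/uL) considered substantial for
#'   untreated patients with high CD4. Default 100.
#' @param cd4_on_art CD4 threshold (cells/uL) for suppressed treated patients.
#'   Default 200.
#' @param vl_suppressed,vl_low Viral-load thresholds (copies/mL) bounding
#'   suppression (<=50) and low-level viraemia (51-200). Defaults 50 and 200.
#' @param vl_high Untreated viral load (copies/mL) considered high. Default
#'   100000.
#' @param diagnosis_window_months Months after HIV diagnosis during which an
#'   episode fires the recent-diagnosis rule. Default 1.
#' @param aids_persistent If `TRUE` the AIDS rule keeps firing at every
#'   episode after the diagnosis; by default it is scoped to the diagnosis
#'   month, mirroring the construction of the recent-diagnosis rule.
#' @param fallback_months Interval used when no rule is satisfiable (e.g. a
#'   patient with no usable CD4 or viral load and no event flags). Default 4,
#'   the midpoint of the rule set.
#' @return A list of class `eic_rule_config`.
#' @export
eic_rule_config <- function(intervals = list(),
                            routine_months = 6,
                            cd4_low = 350, cd4_high = 500,
                            cd4_drop_high = 100, cd4_on_art = 200,
                            vl_suppressed = 50, vl_low = 200, vl_high = 1e5,
                            diagnosis_window_months = 1,
                            aids_persistent = FALSE,
                            fallback_months = 4) {
  iv <- list(diagnosis = 2, aids = 2, art_start = 2, art_switch = 2,
             cd4_le350_drop = 2, cd4_le350_stable = 4, cd4_351_499 = 4,
             cd4_ge500_drop_ge100 = 4, cd4_ge500_high_vl = 4,
             cd4_ge500_low_vl = routine_months,
             vl_gt200 = 2, vl_low_not_blip = 2, vl_low_blip = 4,
             vl_supp_cd4_le200 = 4, vl_supp_cd4_gt200 = routine_months)
  unknown <- setdiff(names(intervals), RULE_IDS)
  if (length(unknown)) {
    stop("unknown rule identifier(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  iv[names(intervals)] <- intervals
  iv <- lapply(iv, as.numeric)
  if (any(vapply(iv, function(v) !is.finite(v) || v <= 0 || v != round(v),
                 logical(1)))) {
    stop("rule intervals must be positive whole months", call. = FALSE)
  }
  thr <- c(cd4_low = cd4_low, cd4_high = cd4_high,
           cd4_drop_high = cd4_drop_high, cd4_on_art = cd4_on_art,
           vl_suppressed = vl_suppressed, vl_low = vl_low, vl_high = vl_high,
           fallback_months = fallback_months,
           diagnosis_window_months = diagnosis_window_months)
  if (any(!is.finite(thr) | thr <= 0)) {
    stop("rule thresholds must be positive and finite", call. = FALSE)
  }
  structure(
    list(intervals = iv,
         cd4_low = cd4_low, cd4_high = cd4_high,
         cd4_drop_high = cd4_drop_high, cd4_on_art = cd4_on_art,
         vl_suppressed = vl_suppressed, vl_low = vl_low, vl_high = vl_high,
         diagnosis_window_months = diagnosis_window_months,
         aids_persistent = isTRUE(aids_persistent),
         fallback_months = as.numeric(fallback_months)),
    class = "eic_rule_config"
  )
}

#' @export
print.eic_rule_config <- function(x, ...) {
  cat("<eic_rule_config>\n")
  cat(sprintf("  intervals (months): %s\n",
              paste(sprintf("%s=%g", names(x$intervals),
                            unlist(x$intervals)), collapse = " ")))
  cat(sprintf("  CD4 thresholds: %g/%g (untreated), %g (on ART), drop %g\n",
              x$cd4_low, x$cd4_high, x$cd4_on_art, x$cd4_drop_high))
  cat(sprintf("  VL thresholds: %g/%g, high %g; fallback %g months\n",
              x$vl_suppressed, x$vl_low, x$vl_high, x$fallback_months))
  invisible(x)
}

#' Read / write a rule configuration as YAML
#'
#' The on-disk form is a flat YAML mapping of the constructor's arguments,
#' with per-rule intervals nested under `intervals`; absent keys take the
#' defaults of [eic_rule_config()].
#'
#' @param path YAML file path.
#' @return `read_rule_config()` returns an `eic_rule_config`;
#'   `write_rule_config()` returns `path` invisibly.
#' @export
read_rule_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw), names(formals(eic_rule_config)))]
  do.call(eic_rule_config, args)
}

#' @rdname read_rule_config
#' @param config An `eic_rule_config`.
#' @export
write_rule_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
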