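# MOE / SE / CV algebra and region-level error propagation.
#
# Published small-area survey estimates come with margins of error (MOE), the
# half-width of a 90% confidence interval, on the same scale as the estimate.
# All propagation below follows the US Census Bureau root-sum-of-squares rules
# for sums of estimates and the derived-proportion / derived-ratio formulas.

#' Convert a margin of error to a standard error
#'
#' Published MOEs are 90% interval half-widths, so the standard error is
#' `moe / 1.645`. The inverse is [se_to_moe()].
#'
#' @param moe Nonnegative numeric vector of margins of error.
#' @return Numeric vector of standard errors, same units as `moe`.
#' @examples
#' moe_to_se(114.5) # 69.6
#' @export
moe_to_se <- function(moe) {
  assert_numeric_finite(moe, "moe")
  if (any(moe < 0)) stop_cvr("moe must be nonnegative", "cvr_domain_error")
  moe / Z90
}

#' @rdname moe_to_se
#' @param se Nonnegative numeric vector of standard errors.
#' @export
se_to_moe <- function(se) {
  assert_numeric_finite(se, "se")
  if (any(se < 0)) stop_cvr("se must be nonnegative", "cvr_domain_error")
  se * Z90
}

#' Coefficient of variation of a published estimate
#'
#' `cv = moe / (1.645 * estimate)`, the standard error as a share of the
#' estimate. A zero estimate with zero MOE is a fully satisfied cell and
#' returns 0; a zero estimate with positive MOE returns `Inf` so that
#' constraint checks fail loudly rather than silently passing.
#'
#' @param estimate Nonnegative numeric vector of estimates.
#' @param moe Nonnegative numeric vector of margins of error (same units).
#' @return Numeric vector of coefficients of variation.
#' @examples
#' cv(94.9, 3.6)  # 0.023
#' cv(5000, 822)  # 0.1
#' @export
cv <- function(estimate, moe) {
  assert_numeric_finite(estimate, "estimate")
  assert_numeric_finite(moe, "moe")
  if (any(estimate < 0)) stop_cvr("estimate must be nonnegative", "cvr_domain_error")
  if (any(moe < 0)) stop_cvr("moe must be nonnegative", "cvr_domain_error")
  se <- moe / Z90
  out <- ifelse(estimate > 0, se / estimate, ifelse(se > 0, Inf, 0))
  as.numeric(out)
}

# cv from estimate and standard error, same zero conventions (internal hot path)
cv_from_se <- function(estimate, se) {
  ifelse(estimate > 0, se / estimate, ifelse(se > 0, Inf, 0))
}

#' 90% confidence interval of an estimate
#'
#' @param estimate Numeric vector of estimates.
#' @param moe Nonnegative numeric vector of margins of error.
#' @param nonnegative Truncate the lower bound at zero (the default; counts and
#'   proportions cannot be negative).
#' @return A tibble with columns `lower` and `upper`.
#' @examples
#' cv_interval(169, 174) # (0, 343)
#' @export
cv_interval <- function(estimate, moe, nonnegative = TRUE) {
  assert_numeric_finite(estimate, "estimate")
  assert_numeric_finite(moe, "moe")
  if (any(moe < 0)) stop_cvr("moe must be nonnegative", "cvr_domain_error")
  lower <- estimate - moe
  if (nonnegative) lower <- pmax(lower, 0)
  tibble::tibble(lower = lower, upper = estimate + moe)
}

#' Aggregate independent count estimates
#'
#' Root-sum-of-squares propagation for a sum of estimates: the aggregate
#' estimate is the sum of the member estimates and the aggregate SE is
#' `sqrt(sum(se^2))`, treating member sampling errors as independent.
#'
#' @param values A data frame with columns `estimate` and `se`, one row per
#'   member estimate.
#' @return A one-row tibble with columns `estimate` and `se`.
#' @examples
#' aggregate_count(data.frame(estimate = c(10, 20), se = c(3, 4))) # (30, 5)
#' @export
aggregate_count <- function(values) {
  if (!is.data.frame(values) || !all(c("estimate", "se") %in% names(values))) {
    stop_cvr("values must be a data frame with columns estimate, se", "cvr_contract_error")
  }
  if (nrow(values) == 0L) {
    stop_cvr("cannot aggregate an empty set of estimates", "cvr_domain_error")
  }
  tibble::tibble(
    estimate = sum(values$estimate),
    se = sqrt(sum(values$se^2))
  )
}

#' Standard error of a derived proportion or ratio mean
#'
#' For a derived value `p = num / den` built from two published estimates, the
#' propagation depends on whether the numerator counts a subset of the
#' denominator's universe:
#'
#' * `kind = "proportion"` (numerator is a subset):
#'   `se = sqrt(num_se^2 - p^2 * den_se^2) / den`. When the radicand is
#'   negative (possible with published MOEs) the ratio form below is used
#'   instead, and the fallback is flagged.
#' * `kind = "mean"` (ratio of two distinct quantities):
#'   `se = sqrt(num_se^2 + p^2 * den_se^2) / den`.
#'
#' @param num_est,num_se Numerator estimate and standard error.
#' @param den_est,den_se Denominator estimate and standard error.
#' @param kind `"proportion"` or `"mean"`.
#' @return A tibble with columns `estimate` (the ratio), `se`, and `fallback`
#'   (logical; `TRUE` where the proportion formula fell back to the ratio form).
#' @examples
#' derived_se(50, 6, 100, 8, "proportion") # se = 0.01 * sqrt(20)
#' @export
derived_se <- function(num_est, num_se, den_est, den_se, kind = c("proportion", "mean")) {
  kind <- match.arg(kind)
  n <- max(length(num_est), length(den_est))
  num_est <- rep_len(num_est, n); num_se <- rep_len(num_se, n)
  den_est <- rep_len(den_est, n); den_se <- rep_len(den_se, n)
  if (any(den_est <= 0)) {
    stop_cvr("denominator estimate must be positive (zero-denominator areas are filtered upstream)",
             "cvr_domain_error")
  }
  p <- num_est / den_est
  minus <- num_se^2 - p^2 * den_se^2
  plus <- num_se^2 + p^2 * den_se^2
  if (kind == "proportion") {
    fallback <- minus < 0
    rad <- ifelse(fallback, plus, minus)
  } else {
    fallback <- rep(FALSE, n)
    rad <- plus
  }
  tibble::tibble(estimate = p, se = sqrt(rad) / den_est, fallback = fallback)
}

#' Region-level estimates, standard errors and CVs
#'
#' Aggregates a set of areas to one region and propagates the published
#' uncertainty: counts via [aggregate_count()]; proportions and means by
#' aggregating numerator and denominator separately and applying
#' [derived_se()] to the aggregates. The small-proportion exemption flag
#' (`exempt`) marks proportion variables whose region-level estimate is below
#' 5%, for which the CV constraint is waived.
#'
#' @param table An area table (see [read_area_table()]).
#' @param region Character vector of `area_id`s forming the region.
#' @param specs A variable specification tibble (see [variable_spec()]).
#' @return A tibble with one row per variable: `variable`, `kind`, `estimate`,
#'   `se`, `moe`, `cv`, `exempt`, `fallback`.
#' @export
region_cv_table <- function(table, region, specs) {
  specs <- validate_specs(specs, table)
  if (length(region) == 0L) stop_cvr("region must contain at least one area", "cvr_domain_error")
  idx <- match(region, table$area_id)
  if (anyNA(idx)) {
    stop_cvr(paste0("unknown area id(s): ", paste(region[is.na(idx)], collapse = ", ")),
             "cvr_contract_error")
  }
  purrr::pmap_dfr(specs, function(name, kind, num_est, num_moe, den_est, den_moe, cv_target) {
    ne <- table[[num_est]][idx]
    nse <- table[[num_moe]][idx] / Z90
    if (kind == "count") {
      agg <- aggregate_count(data.frame(estimate = ne, se = nse))
      est <- agg$estimate; se <- agg$se; fb <- FALSE
    } else {
      de <- table[[den_est]][idx]
      dse <- table[[den_moe]][idx] / Z90
      dsum <- sum(de)
      if (dsum <= 0) {
        return(tibble::tibble(
          variable = name, kind = kind, estimate = NaN, se = NaN,
          moe = NaN, cv = NaN, exempt = FALSE, fallback = FALSE
        ))
      }
      d <- derived_se(sum(ne), sqrt(sum(nse^2)), dsum, sqrt(sum(dse^2)), kind)
      est <- d$estimate; se <- d$se; fb <- d$fallback
    }
    tibble::tibble(
      variable = name, kind = kind, estimate = est, se = se,
      moe = se * Z90, cv = cv_from_se(est, se),
      exempt = kind == "proportion" && is.finite(est) && est < 0.05,
      fallback = fb
    )
  })
}
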