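# Welch's t-test and Cohen's d between result sets, from per-fold accuracy
# vectors or from published summary statistics (mean, SD, n).

as_summary <- function(x) {
  if (is.list(x) && all(c("mean", "sd", "n") %in% names(x))) {
    list(mean = x$mean, sd = x$sd, n = x$n)
  } else {
    stopifnot(is.numeric(x), length(x) >= 2)
    list(mean = mean(x), sd = stats::sd(x), n = length(x))
  }
}

#' Welch's t-test and Cohen's d between two result sets
#'
#' Accepts per-fold accuracy vectors, or `list(mean =, sd =, n =)` summary
#' statistics (e.g. published tables). Two-sided p-value with
#' Welch--Satterthwaite degrees of freedom; Cohen's d uses the unweighted
#' pooled SD `sqrt((sd_a^2 + sd_b^2) / 2)`.
#'
#' @param a,b Numeric vectors or summary lists; `a` is the focal method.
#' @return Tibble: `delta` (mean_a - mean_b), `t`, `df`, `p`, `d`.
#' @export
welch_stats <- function(a, b) {
  sa <- as_summary(a); sb <- as_summary(b)
  stopifnot(sa$n >= 2, sb$n >= 2, sa$sd >= 0, sb$sd >= 0)
  delta <- sa$mean - sb$mean
  va <- sa$sd^2 / sa$n
  vb <- sb$sd^2 / sb$n
  se <- sqrt(va + vb)
  if (se == 0) {
    t <- if (delta == 0) 0 else sign(delta) * Inf
    if (is.infinite(t)) {
      warning("zero pooled variance with nonzero difference: t is infinite",
              call. = FALSE)
    }
    df <- sa$n + sb$n - 2
  } else {
    t <- delta / se
    df <- (va + vb)^2 / (va^2 / (sa$n - 1) + vb^2 / (sb$n - 1))
  }
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df)
  pooled <- sqrt((sa$sd^2 + sb$sd^2) / 2)
  d <- if (pooled == 0) {
    if (delta == 0) 0 else sign(delta) * Inf
  } else delta / pooled
  tibble::tibble(delta = delta, t = t, df = df, p = p, d = d)
}

#' Published subject-independent benchmark accuracies
#'
#' Mean and SD of per-fold accuracy (%) for this architecture and key
#' baselines on the SEED (15 LOSO folds), THU-EP (10 leave-8-out folds) and
#' FACED (10 leave-12-out folds) corpora, as reported in the EEG emotion
#' recognition benchmark literature. Used to recompute comparison
#' statistics; the licensed datasets themselves are not shipped.
#'
#' @return Tibble: `dataset`, `method`, `acc_mean`, `acc_sd`, `n_folds`.
#' @export
reference_results <- function() {
  path <- system.file("extdata", "reference_results.csv", package = "msgm")
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Comparison statistics of the focal method against each baseline
#'
#' Recomputes, per dataset, Welch's t, two-sided p and Cohen's d of the
#' focal method (`"MSGM"`) against every baseline row from the summary
#' accuracies, using each dataset's fold count as the sample size.
#'
#' @param reference Tibble as [reference_results()].
#' @param focal Method name treated as the focal result set.
#' @return Tibble: dataset, method, focal/baseline means, `delta`, `t`,
#'   `df`, `p`, `d`.
#' @export
compare_to_reference <- function(reference = reference_results(),
                                 focal = "MSGM") {
  ref <- dplyr::filter(reference, .data$method == focal)
  base <- dplyr::filter(reference, .data$method != focal)
  purrr::pmap_dfr(base, function(dataset, method, acc_mean, acc_sd, n_folds, ...) {
    f <- dplyr::filter(ref, .data$dataset == !!dataset)
    if (nrow(f) != 1L) return(NULL)
    st <- welch_stats(list(mean = f$acc_mean, sd = f$acc_sd, n = f$n_folds),
                      list(mean = acc_mean, sd = acc_sd, n = n_folds))
    dplyr::bind_cols(
      tibble::tibble(dataset = dataset, method = method,
                     focal_acc = f$acc_mean, baseline_acc = acc_mean), st)
  })
}
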