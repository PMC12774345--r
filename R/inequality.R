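# Theil-T (GE(1)) inequality with additive between/within-group
# decomposition, polarization ratio, and percent-between.

#' Theil-T inequality decomposition
#'
#' With equal unit shares and grand mean `mu`:
#' `T_total = (1/n) sum (x_i/mu) log(x_i/mu)`;
#' `T_within = sum_g (n_g/n) (mu_g/mu) T_g` with `T_g` the within-group
#' Theil-T; `T_between = sum_g (n_g/n) (mu_g/mu) log(mu_g/mu)`.
#' `T_between + T_within = T_total` holds by construction (to numerical
#' precision). The polarization index is `T_between / T_within` and the
#' percent-between `100 * T_between / T_total`. Units are unweighted by
#' default (every unit counts once); supply `weights` for a
#' population-weighted decomposition.
#'
#' @param values Positive numeric vector, one entry per unit.
#' @param groups Group label per unit.
#' @param weights Optional non-negative unit weights (default equal).
#' @return List with `T_total`, `T_between`, `T_within`, `polarization`
#'   (`Inf` with `degenerate_within = TRUE` when within-inequality is 0),
#'   `pct_between` (`NA` with `degenerate_total = TRUE` under perfect
#'   equality), and `group_table` (tibble: group, n, mean, T_g).
#' @export
theil_decomposition <- function(values, groups, weights = NULL) {
  if (any(!is.finite(values)) || any(values <= 0)) {
    bad <- which(!is.finite(values) | values <= 0)
    stop("Theil-T requires strictly positive values; offending unit(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  n <- length(values)
  stopifnot(length(groups) == n)
  w <- if (is.null(weights)) rep(1, n) else weights
  stopifnot(length(w) == n, all(w >= 0), sum(w) > 0)
  sw <- w / sum(w)
  mu <- sum(sw * values)

  theil_t <- function(x, s) {
    s <- s / sum(s)
    m <- sum(s * x)
    sum(s * (x / m) * log(x / m))
  }

  t_total <- theil_t(values, sw)
  gset <- split(seq_len(n), groups)
  gt <- lapply(names(gset), function(g) {
    i <- gset[[g]]
    sg <- sum(sw[i])
    mg <- sum(sw[i] * values[i]) / sg
    tibble::tibble(group = g, n = length(i), share = sg, mean = mg,
                   T_g = theil_t(values[i], sw[i]))
  })
  gt <- dplyr::bind_rows(gt)
  t_within <- sum(gt$share * (gt$mean / mu) * gt$T_g)
  t_between <- sum(gt$share * (gt$mean / mu) * log(gt$mean / mu))

  degen_total <- t_total <= .Machine$double.eps
  degen_within <- t_within <= .Machine$double.eps
  list(
    T_total = t_total, T_between = t_between, T_within = t_within,
    polarization = if (degen_within) Inf else t_between / t_within,
    degenerate_within = degen_within,
    pct_between = if (degen_total) NA_real_ else 100 * t_between / t_total,
    degenerate_total = degen_total,
    group_table = gt[, c("group", "n", "mean", "T_g")]
  )
}
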