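#' New-cluster accumulation along one genome ordering
#'
#' Walks the genomes in the given order and counts, at each step j, the
#' architectures present in genome j but absent from all earlier genomes.
#' The counts over all steps sum to the pan size.
#'
#' @param presence A binarized abundance table from [binarize()].
#' @param order Character vector: a permutation of the genome ids.
#' @return Integer vector `y` of length `length(order)`; `y[1]` is the
#'   number of architectures in the first genome.
#' @export
accumulation_curve <- function(presence, order) {
  m <- pa_matrix(presence)
  if (!setequal(order, rownames(m)) || length(order) != nrow(m)) {
    abort("`order` must be a permutation of the genome ids in `presence`")
  }
  m <- m[order, , drop = FALSE] > 0
  seen <- rep(FALSE, ncol(m))
  y <- integer(nrow(m))
  for (j in seq_len(nrow(m))) {
    new <- m[j, ] & !seen
    y[j] <- sum(new)
    seen <- seen | new
  }
  y
}

#' Fit the Heaps' law decay to pooled accumulation counts
#'
#' Fits the power-law decay `y_new(j) = kappa * j^(-alpha)` to observed
#' new-cluster counts by nonlinear least squares on the natural scale
#' (zero counts are common, so no log transform by default). The decay
#' parameter classifies pan-genome openness: `alpha < 1` means open (new
#' clusters keep arriving as genomes are added), `alpha > 1` closed;
#' exactly 1 is reported as open with a boundary note. Initial values are
#' `kappa0` = mean count at j = 2 and `alpha0` = 1.
#'
#' @param data A data frame with columns `j` (genome index, >= 2) and `y`
#'   (new-cluster count at that index).
#' @param log_scale If `TRUE`, fit by least squares on
#'   `log(y + 1) ~ log(kappa) - alpha * log(j)` instead — an alternative
#'   for sensitivity analysis, not the default contract.
#' @return A `heaps_fit` object; see [heaps_fit()].
#' @export
fit_heaps_decay <- function(data, log_scale = FALSE) {
  check_columns(data, c("j", "y"), "`data`")
  if (any(data$j < 2)) {
    abort("`data$j` must be >= 2: the first genome contributes no decay information")
  }
  if (nrow(data) == 0 || all(data$y == 0)) {
    return(new_heaps_fit(
      kappa = NA_real_, alpha = NA_real_, rss = NA_real_,
      converged = FALSE, openness = "degenerate",
      note = "all new-cluster counts are zero (fully closed sample)",
      data = tibble::as_tibble(data)
    ))
  }
  kappa0 <- mean(data$y[data$j == min(data$j)])
  if (!is.finite(kappa0) || kappa0 <= 0) kappa0 <- max(mean(data$y), 0.5)

  if (log_scale) {
    fit <- stats::lm(log(y + 1) ~ log(j), data = data)
    alpha <- -unname(stats::coef(fit)[2])
    kappa <- exp(unname(stats::coef(fit)[1]))
    rss <- sum(stats::resid(fit)^2)
    converged <- TRUE
  } else {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ kappa * j^(-alpha),
        data = data,
        start = list(kappa = kappa0, alpha = 1),
        lower = c(kappa = 1e-12, alpha = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      return(new_heaps_fit(
        kappa = NA_real_, alpha = NA_real_, rss = NA_real_,
        converged = FALSE, openness = "degenerate",
        note = paste("fit failed:", conditionMessage(fit)),
        data = tibble::as_tibble(data)
      ))
    }
    est <- stats::coef(fit)
    kappa <- unname(est["kappa"])
    alpha <- unname(est["alpha"])
    rss <- sum(stats::resid(fit)^2)
    converged <- fit$convInfo$isConv %||% TRUE
  }

  openness <- if (alpha > 1) "closed" else "open"
  note <- if (alpha == 1) "alpha exactly at the open/closed boundary" else NA_character_
  new_heaps_fit(
    kappa = kappa, alpha = alpha, rss = rss, converged = converged,
    openness = openness, note = note, data = tibble::as_tibble(data)
  )
}

new_heaps_fit <- function(kappa, alpha, rss, converged, openness, note, data,
                          n_permutations = NA_integer_, seed = NA_integer_) {
  structure(
    list(
      kappa = kappa, alpha = alpha, rss = rss, converged = converged,
      openness = openness, note = note, data = data,
      n_permutations = n_permutations, seed = seed
    ),
    class = "heaps_fit"
  )
}

#' Heaps' law openness estimate for a genome collection
#'
#' Estimates pan-genome openness by pooling new-cluster accumulation
#' counts over random genome orderings and fitting the decay
#' `y_new(j) = kappa * j^(-alpha)` with [fit_heaps_decay()]. Points from
#' every permutation at positions j = 2..n are pooled into a single
#' least-squares fit (per-j means are available via `use_means` and
#' coincide in expectation). Orderings are sampled independently with a
#' single seeded generator; the result is deterministic given `seed`.
#'
#' @param presence A binarized abundance table from [binarize()].
#' @param n_permutations Number of random genome orderings (default 5000).
#' @param seed Integer seed for the permutation draw.
#' @param use_means Fit per-j mean counts instead of pooled points.
#' @param log_scale Passed to [fit_heaps_decay()].
#' @return A `heaps_fit` object with elements `kappa`, `alpha`, `rss`,
#'   `converged`, `openness` (`"open"`, `"closed"` or `"degenerate"`),
#'   `note`, the pooled `data`, `n_permutations` and `seed`. Has
#'   [tidy()], [glance()], [autoplot()] and print methods.
#' @export
heaps_fit <- function(presence, n_permutations = 5000, seed = 1,
                      use_means = FALSE, log_scale = FALSE) {
  m <- pa_matrix(presence)
  n <- nrow(m)
  if (n < 3) {
    abort("Heaps fitting needs at least 3 genomes")
  }
  if (n_permutations < 1) {
    abort("`n_permutations` must be at least 1")
  }
  genomes <- rownames(m)
  pooled <- local_seed(seed, {
    purrr::map(seq_len(n_permutations), function(i) {
      accumulation_curve(presence, sample(genomes))[-1]
    })
  })
  data <- tibble::tibble(
    j = rep(seq(2, n), times = n_permutations),
    y = unlist(pooled)
  )
  if (use_means) {
    data <- data |>
      dplyr::group_by(.data$j) |>
      dplyr::summarise(y = mean(.data$y), .groups = "drop")
  }
  out <- fit_heaps_decay(data, log_scale = log_scale)
  out$n_permutations <- as.integer(n_permutations)
  out$seed <- as.integer(seed)
  out
}

#' Heaps' law fit with genomes excluded
#'
#' Refits openness on the presence matrix with the given genomes removed
#' and architectures private to them dropped — the standard check that a
#' single divergent genome (non-uniform sampling) is not driving the
#' openness estimate.
#'
#' @inheritParams heaps_fit
#' @param excluded Character vector of genome ids to drop; ids absent
#'   from the matrix are ignored.
#' @return A `heaps_fit` object.
#' @export
heaps_fit_excluding <- function(presence, excluded, n_permutations = 5000,
                                seed = 1, use_means = FALSE, log_scale = FALSE) {
  kept <- dplyr::filter(presence, !(.data$genome_id %in% excluded))
  if (nrow(kept) < 3) {
    abort("fewer than 3 genomes remain after exclusion")
  }
  vals <- pa_matrix(kept)
  nonzero <- colnames(vals)[colSums(vals) > 0]
  kept <- kept[, c("genome_id", nonzero)]
  heaps_fit(kept,
    n_permutations = n_permutations, seed = seed,
    use_means = use_means, log_scale = log_scale
  )
}

# Evaluate code under a temporary RNG state.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  )
  set.seed(seed)
  force(code)
}

#' @export
print.heaps_fit <- function(x, ...) {
  if (x$openness == "degenerate") {
    cat("Heaps' law fit: degenerate (", x$note, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf(
    "Heaps' law fit: y_new(j) = %.4g * j^(-%.4g)\n", x$kappa, x$alpha
  ))
  cat(sprintf(
    "  alpha = %.4g -> %s pan-genome%s\n", x$alpha, x$openness,
    if (!is.na(x$note)) paste0(" (", x$note, ")") else ""
  ))
  cat(sprintf(
    "  %d pooled points, rss = %.4g, converged = %s\n",
    nrow(x$data), x$rss, x$converged
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.heaps_fit <- function(x, ...) {
  tibble::tibble(
    term = c("kappa", "alpha"),
    estimate = c(x$kappa, x$alpha)
  )
}

#' @exportS3Method generics::glance
glance.heaps_fit <- function(x, ...) {
  tibble::tibble(
    kappa = x$kappa,
    alpha = x$alpha,
    openness = x$openness,
    rss = x$rss,
    converged = x$converged,
    n_points = nrow(x$data),
    n_permutations = x$n_permutations,
    seed = x$seed
  )
}
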