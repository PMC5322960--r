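#' Fleiss' kappa for multiple raters
#'
#' Chance-corrected agreement for `n` raters assigning categorical labels to
#' `N` items: `kappa = (P_bar - P_e) / (1 - P_e)`, where `P_bar` is the mean
#' per-item pairwise agreement and `P_e` the chance agreement from the marginal
#' category proportions. Equals 1 exactly when all raters agree on all items.
#' The large-sample z statistic of the kappa-zero test is included.
#'
#' @param ratings An items x categories matrix of counts; every row must sum to
#'   the same number of raters (at least 2).
#' @return An object of class `fleiss_kappa`: a list with `kappa`, `z`,
#'   `p_value`, `p_bar`, `p_e`, `n_items`, `n_raters`, `categories`. When a
#'   single category absorbs all ratings, `P_e = 1` and `kappa` is undefined
#'   (`NA`) and reported as such.
#' @examples
#' m <- rbind(c(3, 0), c(0, 3), c(3, 0))
#' fleiss_kappa(m)
#' @export
fleiss_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (any(ratings < 0) || any(ratings != round(ratings))) {
    stop("ratings must be a matrix of non-negative counts", call. = FALSE)
  }
  raters <- rowSums(ratings)
  if (length(unique(raters)) != 1L) {
    stop("every item must be rated by the same number of raters", call. = FALSE)
  }
  n <- raters[1]
  if (n < 2) stop("at least two raters are required", call. = FALSE)
  N <- nrow(ratings)
  p_j <- colSums(ratings) / (N * n)
  p_i <- (rowSums(ratings^2) - n) / (n * (n - 1))
  p_bar <- mean(p_i)
  p_e <- sum(p_j^2)
  if (isTRUE(all.equal(p_e, 1))) {
    kappa <- NA_real_
    z <- NA_real_
    p_value <- NA_real_
  } else {
    kappa <- (p_bar - p_e) / (1 - p_e)
    # Fleiss' large-sample standard error under kappa = 0
    se0 <- sqrt(2 / (N * n * (n - 1))) *
      sqrt(p_e - (2 * n - 3) * p_e^2 + 2 * (n - 2) * sum(p_j^3)) / (1 - p_e)
    z <- kappa / se0
    p_value <- 2 * stats::pnorm(-abs(z))
  }
  structure(
    list(
      kappa = kappa, z = z, p_value = p_value,
      p_bar = p_bar, p_e = p_e,
      n_items = N, n_raters = as.integer(n),
      categories = colnames(ratings) %||% as.character(seq_len(ncol(ratings)))
    ),
    class = "fleiss_kappa"
  )
}

#' @export
print.fleiss_kappa <- function(x, ...) {
  cat("Fleiss' kappa for", x$n_raters, "raters on", x$n_items, "items\n")
  if (is.na(x$kappa)) {
    cat("  kappa undefined: a single category absorbs all ratings (P_e = 1)\n")
  } else {
    cat(sprintf(
      "  kappa = %.4f  (P_bar = %.4f, P_e = %.4f, z = %.2f)\n",
      x$kappa, x$p_bar, x$p_e, x$z
    ))
  }
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' @method glance fleiss_kappa
#' @export
glance.fleiss_kappa <- function(x, ...) {
  tibble::tibble(
    kappa = x$kappa, z = x$z, p.value = x$p_value,
    p.bar = x$p_bar, p.e = x$p_e,
    n.items = x$n_items, n.raters = x$n_raters
  )
}
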