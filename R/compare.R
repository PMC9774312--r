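#' Compare perfusion metrics between two waveform groups
#'
#' Per-metric mean, standard deviation and a two-sided two-sample test
#' between two groups of perfusion outcomes (e.g. a batch of synthetic
#' manual waveforms against replicates of the mechanical waveform).
#' The default test is Welch's t; a permutation test on the difference of
#' means is available for small or non-normal groups.
#'
#' @param group_a,group_b lists of `perfusion_metrics` objects (or
#'   data.frames with columns `CO`, `CPP`, `CF`), n >= 2 each.
#' @param method `"welch"` (default) or `"permutation"`.
#' @param n_perm permutation count for `method = "permutation"`.
#' @return An object of class `group_comparison`: data.frame with one row
#'   per metric (`mean_a`, `sd_a`, `mean_b`, `sd_b`, `p_value`).
#' @export
compare_waveforms <- function(group_a, group_b,
                              method = c("welch", "permutation"),
                              n_perm = 10000) {
  method <- match.arg(method)
  to_df <- function(g) {
    if (is.data.frame(g)) g[c("CO", "CPP", "CF")]
    else do.call(rbind, lapply(g, function(m)
      data.frame(CO = m$CO, CPP = m$CPP, CF = m$CF)))
  }
  a <- to_df(group_a); b <- to_df(group_b)
  if (nrow(a) < 2 || nrow(b) < 2)
    stop("need at least 2 waveforms per group", call. = FALSE)
  rows <- lapply(c("CO", "CPP", "CF"), function(m) {
    xa <- a[[m]]; xb <- b[[m]]
    p <- if (method == "welch") {
      if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
        if (mean(xa) == mean(xb)) 1 else 0
      } else stats::t.test(xa, xb)$p.value
    } else {
      permutation_p(xa, xb, n_perm)
    }
    data.frame(metric = m, n_a = length(xa), mean_a = mean(xa),
               sd_a = stats::sd(xa), n_b = length(xb), mean_b = mean(xb),
               sd_b = stats::sd(xb), p_value = p)
  })
  structure(do.call(rbind, rows), class = c("group_comparison",
                                            "data.frame"))
}

# two-sided permutation p-value for a difference of group means
permutation_p <- function(xa, xb, n_perm) {
  obs <- abs(mean(xa) - mean(xb))
  pool <- c(xa, xb)
  na <- length(xa)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pool), na)
    if (abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-15)
      hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

#' @export
print.group_comparison <- function(x, ...) {
  for (i in seq_len(nrow(x)))
    cat(sprintf(
      "%-3s  A: %.5f +/- %.5f   B: %.5f +/- %.5f   p = %.3g\n",
      x$metric[i], x$mean_a[i], x$sd_a[i], x$mean_b[i], x$sd_b[i],
      x$p_value[i]))
  invisible(x)
}
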