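#' @export
print.evaluation_framework <- function(x, ...) {
  cat("Evaluation framework:", length(x$dimensions), "dimension(s),",
      nrow(x$assignment), "criteria\n")
  for (d in names(x$dimensions)) {
    cat(" ", d, ":", paste(x$dimensions[[d]], collapse = ", "), "\n")
  }
  if (length(x$deleted)) {
    cat("  deleted (below cutoff):", paste(x$deleted, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.consensus_report <- function(x, ...) {
  cat(sprintf("Expert consensus: gap ratio %.3f%% (threshold %.1f%%) - %s\n",
              x$gap_ratio_pct, x$threshold_pct,
              if (x$stable) "stable" else "NOT stable"))
  if (x$skipped_cells > 0) {
    cat(sprintf("  %d zero-mean cell(s) skipped in the gap ratio\n", x$skipped_cells))
  }
  invisible(x)
}

#' @export
print.weight_set <- function(x, ...) {
  cat("DANP influence weights (limit supermatrix,",
      x$convergence$iterations, "squarings)\n")
  print(x$weights, row.names = FALSE, digits = 4)
  flags <- c(if (x$convergence$cyclic) "cyclic",
             if (x$convergence$reducible) "reducible")
  if (length(flags)) cat("  flags:", paste(flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.topsis_result <- function(x, ...) {
  cat("TOPSIS result\n")
  tab <- data.frame(alternative = names(x$proximity),
                    d_pos = x$separation_pos,
                    d_neg = x$separation_neg,
                    proximity = x$proximity)
  print(tab, row.names = FALSE, digits = 4)
  cat("Ranking:", paste(x$ranking, collapse = " > "), "\n")
  invisible(x)
}

#' @export
print.run_report <- function(x, ...) {
  cat(render_report(x, "markdown"), sep = "\n")
  invisible(x)
}
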