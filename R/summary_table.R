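#' Long-format measurement table
#'
#' All quantifiers report their per-entity measurements in one long format:
#' one row per (scenario, cell, phagosome, metric). The table round-trips
#' losslessly through the comma-delimited writer.
#'
#' @param scenario,metric,units character vectors (recycled).
#' @param cell_id,phagosome_id integer vectors (NA when not applicable).
#' @param value numeric vector.
#' @return a data.frame of class `SummaryTable`.
#' @export
summary_table <- function(scenario = NA_character_, cell_id = NA_integer_,
                          phagosome_id = NA_integer_, metric, value,
                          units = "") {
  df <- data.frame(scenario = as.character(scenario),
                   cell_id = as.integer(cell_id),
                   phagosome_id = as.integer(phagosome_id),
                   metric = as.character(metric),
                   value = as.numeric(value),
                   units = as.character(units),
                   stringsAsFactors = FALSE)
  class(df) <- c("SummaryTable", "data.frame")
  df
}

#' @rdname summary_table
#' @param ... `SummaryTable`s to concatenate.
#' @export
bind_summary <- function(...) {
  df <- do.call(rbind, lapply(list(...), as.data.frame))
  class(df) <- c("SummaryTable", "data.frame")
  df
}

#' Write / read a SummaryTable as CSV
#' @param tab a [summary_table()].
#' @param path file path.
#' @return `path` (write) or a `SummaryTable` (read).
#' @export
write_summary_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_table
#' @export
read_summary_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(scenario = "character",
                                       cell_id = "integer",
                                       phagosome_id = "integer",
                                       metric = "character",
                                       value = "numeric",
                                       units = "character"))
  class(df) <- c("SummaryTable", "data.frame")
  df
}

#' Seeded bootstrap confidence interval for a percent change between groups
#'
#' Resamples both groups with replacement and recomputes
#' 100 * (mean(b) - mean(a)) / mean(a). Used wherever the paper reported a
#' Prism group test: the package replaces inferential tests (beyond the
#' contact-length F-test) with descriptive contrasts plus bootstrap CIs.
#'
#' @param a,b numeric vectors (reference group `a`).
#' @param n_boot number of resamples (default 1e4).
#' @param conf confidence level.
#' @param seed integer seed for the resampling stream.
#' @return list with `pct_change`, `ci` (length-2), `n_boot`.
#' @export
bootstrap_pct_change <- function(a, b, n_boot = 1e4, conf = 0.95, seed = 1L) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  est <- 100 * (mean(b) - mean(a)) / mean(a)
  rs <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      aa <- a[sample.int(length(a), replace = TRUE)]
      bb <- b[sample.int(length(b), replace = TRUE)]
      100 * (mean(bb) - mean(aa)) / mean(aa)
    }, 0)
  })
  alpha <- (1 - conf) / 2
  list(pct_change = est,
       ci = unname(stats::quantile(rs, c(alpha, 1 - alpha))),
       n_boot = n_boot)
}

# run expr under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards
withr_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
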