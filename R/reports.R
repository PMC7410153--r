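## Report rendering.  All internal artifacts keep full precision; rounding
## happens only here, at render time.

#' Design table across vessels and activity states
#'
#' The full sizing table: for every preset (vessel x activity) and every
#' catalog radius, the catheter length realizing the (optionally
#' chamber-corrected) preset resistance, with feasibility flags.
#'
#' @param presets Activity presets, see [activity_presets()].
#' @param catalog,fluid See [design_for_target()].
#' @param chamber_resistance Named vector of per-vessel chamber resistances
#'   to subtract before sizing (default: none).
#' @return A data.frame with columns `activity`, `vessel`, `resistance`,
#'   `fr`, `radius_cm`, `length_cm`, `feasible`, `infeasibility_reason`.
#' @examples
#' dt <- design_table()
#' subset(dt, !feasible)   # the lengths beyond the catalog window
#' @export
design_table <- function(presets = activity_presets(),
                         catalog = catheter_catalog(),
                         fluid = fluid_properties(),
                         chamber_resistance = NULL) {
  .check_presets(presets)
  rows <- lapply(seq_len(nrow(presets)), function(i) {
    corr <- if (is.null(chamber_resistance)) 0 else
      chamber_resistance[[presets$vessel[i]]] %||% 0
    d <- design_for_target(presets$resistance[i], catalog = catalog,
                           fluid = fluid, chamber_resistance = corr)
    d <- d[order(d$fr), ]
    data.frame(activity = presets$activity[i], vessel = presets$vessel[i],
               resistance = presets$resistance[i],
               fr = d$fr, radius_cm = d$radius_cm, length_cm = d$length_cm,
               feasible = d$feasible,
               infeasibility_reason = d$infeasibility_reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(match(out$activity, .activities), match(out$vessel, .vessels), out$fr)
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}

#' Render a report data.frame
#'
#' `"csv"` and `"json"` round-trip losslessly; `"table"` is a fixed-width
#' human-readable rendering with lengths to 1 decimal and percentages to 2.
#'
#' @param report A data.frame (e.g. from [design_table()], [percent_table()]).
#' @param format One of `"table"`, `"csv"`, `"json"`.
#' @param path Optional output file; when `NULL` the rendering is returned
#'   as a character vector (and printed for `"table"`).
#' @return The rendered text, invisibly when written to `path`.
#' @export
render_report <- function(report, format = c("table", "csv", "json"),
                          path = NULL) {
  format <- match.arg(format)
  stopifnot(is.data.frame(report))
  text <- switch(format,
    csv = {
      con <- textConnection("out", "w", local = TRUE)
      utils::write.csv(report, con, row.names = FALSE, quote = FALSE)
      close(con)
      out
    },
    json = jsonlite::toJSON(report, dataframe = "rows", auto_unbox = TRUE,
                            digits = NA, pretty = TRUE),
    table = {
      shown <- report
      num <- vapply(shown, is.numeric, logical(1))
      shown[num] <- lapply(shown[num], function(x) signif(x, 6))
      utils::capture.output(print(shown, row.names = FALSE))
    }
  )
  if (is.null(path)) {
    if (format == "table") cat(text, sep = "\n")
    return(invisible(text))
  }
  writeLines(as.character(text), path)
  invisible(text)
}
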