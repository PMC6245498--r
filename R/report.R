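#' Write the full results bundle of a pipeline run
#'
#' Emits, into `dir`: `result.json` (clusters, significant associations,
#' projection coordinates, manifest), `srv.csv` and `fm.csv` (two-level
#' headers), per-retained-component `rsrv_<k>.csv`, `pc_coordinates.csv`
#' and `eigenvalues.csv`, `clusters.tsv` (cluster id, member event, pole
#' sign, top partner, residual), and `schemes.json` when any attribute was
#' discretized.  All outputs are ordered by the event schema so repeated
#' runs with the same configuration are byte-identical.
#'
#' @param result a `disentangled_result` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_result_bundle <- function(result, dir) {
  stopifnot(inherits(result, "disentangled_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_csv(result$fm, file.path(dir, "fm.csv"))
  write_matrix_csv(result$srv, file.path(dir, "srv.csv"))
  write_pcd_csv(result$pcs, dir)
  clusters_tab <- list()
  json_components <- list()
  for (cmp in result$components) {
    rs <- cmp$rsrv
    write_matrix_csv(structure(list(sr = rs$matrix, schema = rs$schema),
                               class = "srv_matrix"),
                     file.path(dir, sprintf("rsrv_%d.csv", cmp$k)))
    for (ci in seq_along(cmp$clusters)) {
      cl <- cmp$clusters[[ci]]
      for (r in seq_len(nrow(cl))) {
        member <- cl$event[r]
        mine <- cmp$edges[cmp$edges$cluster == ci &
                            (cmp$edges$event_i == member |
                               cmp$edges$event_j == member), , drop = FALSE]
        top <- mine[which.max(abs(mine$residual)), , drop = FALSE]
        partner <- ifelse(top$event_i == member, top$event_j, top$event_i)
        clusters_tab[[length(clusters_tab) + 1L]] <-
          data.frame(component = cmp$k, cluster = ci, member = member,
                     pole = cl$pole[r], top_partner = partner,
                     residual = top$residual, stringsAsFactors = FALSE)
      }
    }
    json_components[[paste0("PC", cmp$k)]] <- list(
      k = cmp$k,
      selected = cmp$selected,
      clusters = lapply(cmp$clusters, function(cl) cl),
      edges = cmp$edges)
  }
  clusters_df <- if (length(clusters_tab)) do.call(rbind, clusters_tab) else
    data.frame(component = integer(0), cluster = integer(0),
               member = character(0), pole = numeric(0),
               top_partner = character(0), residual = numeric(0))
  utils::write.table(clusters_df, file.path(dir, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(result$schemes)) {
    write_schemes(result$schemes, file.path(dir, "schemes.json"))
  }
  jsonlite::write_json(
    list(manifest = result$manifest,
         eigenvalues = result$pcs$eigenvalues,
         retained = result$retained,
         events = result$schema$events,
         components = json_components),
    file.path(dir, "result.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(dir)
}

#' Render a pipeline result as an aligned text report
#'
#' The textual analogue of a shaded association heat map: per retained
#' component, the salient events with their poles and the AR clusters with
#' each edge's residual, significance-marked (`**` for
#' `|residual| > threshold`).
#'
#' @param result a `disentangled_result`.
#' @return character vector of report lines (also usable with
#'   `writeLines`).
#' @export
format_report <- function(result) {
  stopifnot(inherits(result, "disentangled_result"))
  ln <- c(sprintf("Disentangled association report (mode: %s, threshold: %g)",
                  result$srv$mode, result$srv$threshold),
          sprintf("M = %d sequences, %d attributes, I = %d events",
                  result$manifest$M, result$manifest$n_attributes,
                  result$schema$I),
          sprintf("Retained components: %s",
                  paste(result$retained, collapse = ", ")), "")
  for (cmp in result$components) {
    ln <- c(ln, sprintf("== Component PC%d (eigenvalue %.4g) ==", cmp$k,
                        result$pcs$eigenvalues[cmp$k]))
    if (nrow(cmp$selected)) {
      ln <- c(ln, "  salient events (|projection| > stdev rule):")
      ln <- c(ln, sprintf("    %-20s pole %+d   projection %8.3f",
                          cmp$selected$event, cmp$selected$pole,
                          cmp$selected$projection))
    } else {
      ln <- c(ln, "  no salient events")
    }
    if (length(cmp$clusters)) {
      for (ci in seq_along(cmp$clusters)) {
        cl <- cmp$clusters[[ci]]
        ln <- c(ln, sprintf("  cluster %d: %s", ci,
                            paste(sprintf("%s(%+d)", cl$event, cl$pole),
                                  collapse = " ")))
        ed <- cmp$edges[cmp$edges$cluster == ci, , drop = FALSE]
        ln <- c(ln, sprintf("    %-20s -- %-20s  SR %8.3f %s",
                            ed$event_i, ed$event_j, ed$residual,
                            ifelse(abs(ed$residual) > result$srv$threshold,
                                   "**", "")))
      }
    } else {
      ln <- c(ln, "  no clusters")
    }
    ln <- c(ln, "")
  }
  ln
}
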