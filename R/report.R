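#' Self-contained HTML report of a participant-test result
#'
#' Renders a configuration echo plus, depending on the analysis mode, the
#' confusion matrix with overall accuracy and chance level (and the
#' permutation p-value when computed), the RDM as an inline heat map table
#' with a link to its TSV, or summary statistics of the searchlight
#' accuracy map. Everything is embedded in one file.
#'
#' @param results a list with fields among `subject`, `config`, `cv`,
#'   `perm`, `rdm`, `rdm_path`, `map`, `map_path`.
#' @param path output HTML path.
#' @return `path`, invisibly.
#' @export
write_html_report <- function(results, path) {
  if (is.null(results$cv) && is.null(results$rdm) && is.null(results$map))
    stop("nothing to report: no classification, RSA or searchlight result")
  esc <- function(x) {
    x <- gsub("&", "&amp;", as.character(x), fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  parts <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>MVPA report</title>",
    "<style>body{font-family:sans-serif;margin:2em;}",
    "table{border-collapse:collapse;}td,th{border:1px solid #999;",
    "padding:3px 8px;text-align:right;}th{background:#eee;}",
    ".rdm td{width:14px;height:14px;padding:0;border:none;}</style>",
    "</head><body>",
    sprintf("<h1>MVPA report%s</h1>",
            if (!is.null(results$subject))
              paste0(" &mdash; sub-", esc(results$subject)) else ""))

  cfg <- results$config
  if (!is.null(cfg)) {
    show <- cfg[!vapply(cfg, is.null, logical(1))]
    rows <- vapply(names(show), function(k)
      sprintf("<tr><th>%s</th><td>%s</td></tr>", esc(k),
              esc(paste(show[[k]], collapse = " "))), character(1))
    parts <- c(parts, "<h2>Configuration</h2><table>", rows, "</table>")
  }

  if (!is.null(results$cv)) {
    cv <- results$cv
    cm <- cv$confusion
    header <- paste0("<tr><th>predicted \\ target</th>",
                     paste0("<th>", esc(colnames(cm)), "</th>",
                            collapse = ""), "</tr>")
    body <- vapply(seq_len(nrow(cm)), function(i)
      paste0("<tr><th>", esc(rownames(cm)[i]), "</th>",
             paste0("<td>", cm[i, ], "</td>", collapse = ""), "</tr>"),
      character(1))
    parts <- c(parts,
      "<h2>Classification</h2>",
      sprintf("<p>Overall accuracy: <b>%.2f%%</b> (chance %.2f%%)</p>",
              100 * cv$overall_accuracy, 100 * cv$chance_level),
      sprintf("<p>Classifier: %s; %d folds.</p>", esc(cv$classifier),
              length(cv$per_fold_accuracy)),
      "<table>", header, body, "</table>")
    if (!is.null(results$perm)) {
      pm <- results$perm
      parts <- c(parts, sprintf(
        paste0("<p>Permutation test (N = %d label permutations within ",
               "run): p = %.5g; null accuracy mean %.4f.</p>"),
        pm$n_permutations, pm$p_value, mean(pm$null_accuracies)))
    }
  }

  if (!is.null(results$rdm)) {
    D <- results$rdm$distances
    lim <- max(D)
    if (lim == 0) lim <- 1
    cell <- function(v) {
      # blue (0, similar) -> white -> red (max, dissimilar)
      f <- min(max(v / lim, 0), 1)
      if (f < 0.5) {
        w <- f * 2
        sprintf("<td style='background:rgb(%d,%d,255)' title='%.3f'></td>",
                round(60 + 195 * w), round(60 + 195 * w), v)
      } else {
        w <- (f - 0.5) * 2
        sprintf("<td style='background:rgb(255,%d,%d)' title='%.3f'></td>",
                round(255 - 195 * w), round(255 - 195 * w), v)
      }
    }
    rows <- vapply(seq_len(nrow(D)), function(i)
      paste0("<tr>", paste(vapply(D[i, ], cell, character(1)),
                           collapse = ""), "</tr>"), character(1))
    parts <- c(parts,
      "<h2>Representational similarity</h2>",
      sprintf("<p>Metric: %s; %d samples. Blue = similar, red = dissimilar (max %.3f).</p>",
              esc(results$rdm$metric), nrow(D), max(D)),
      if (!is.null(results$rdm_path))
        sprintf("<p>RDM values: <a href='%s'>%s</a></p>",
                esc(basename(results$rdm_path)),
                esc(basename(results$rdm_path))),
      "<table class='rdm'>", rows, "</table>")
  }

  if (!is.null(results$map)) {
    v <- results$map$values
    v <- v[!is.na(v)]
    parts <- c(parts,
      "<h2>Searchlight</h2>",
      sprintf(paste0("<p>Accuracy map: %d voxels evaluated; mean %.4f, ",
                     "max %.4f, min %.4f.</p>"),
              length(v), mean(v), max(v), min(v)),
      if (!is.null(results$map_path))
        sprintf("<p>NIfTI map: <a href='%s'>%s</a></p>",
                esc(basename(results$map_path)),
                esc(basename(results$map_path))))
  }

  parts <- c(parts, "</body></html>")
  writeLines(paste(unlist(parts), collapse = "\n"), path)
  invisible(path)
}
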