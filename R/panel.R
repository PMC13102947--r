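#' Canonical islet cell types
#'
#' The nine cell types the default workflow distinguishes: the four endocrine
#' types (alpha, beta, delta, PP) plus ductal, endothelial, mesenchymal,
#' immune and T cells.
#'
#' @return Character vector of type names.
#' @export
islet_cell_types <- function() {
  c("alpha", "beta", "delta", "pp", "ductal", "endothelial",
    "mesenchymal", "immune", "tcell")
}

#' Default marker panel for mouse islets
#'
#' One canonical marker per cell type with an expression threshold on the
#' log-normalized scale. Thresholds follow the published gating values
#' (Gcg > 2.1, Ins1 > 2.0, Sst > 2, Ppy > 2.2, Krt19 > 0.5, Cd34 > 0.1,
#' Vim > 0.6, Cd86 > 1, Trac > 0.1); the marker-to-type mapping is the
#' canonical islet assignment and can be overridden via [marker_panel()].
#'
#' @return A marker panel `data.frame` with columns `marker`, `threshold`,
#'   `cell_type`, `endocrine`.
#' @export
default_marker_panel <- function() {
  marker_panel(data.frame(
    marker    = c("Gcg", "Ins1", "Sst", "Ppy", "Krt19", "Cd34", "Vim", "Cd86", "Trac"),
    threshold = c(2.1, 2.0, 2.0, 2.2, 0.5, 0.1, 0.6, 1.0, 0.1),
    cell_type = c("alpha", "beta", "delta", "pp", "ductal", "endothelial",
                  "mesenchymal", "immune", "tcell"),
    endocrine = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  ))
}

#' Construct and validate a marker panel
#'
#' @param df `data.frame` with columns `marker` (gene symbol), `threshold`
#'   (positive, on the log-normalized scale), `cell_type` and `endocrine`
#'   (logical).
#' @return The validated panel (class `marker_panel`).
#' @export
marker_panel <- function(df) {
  need <- c("marker", "threshold", "cell_type", "endocrine")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("marker panel is missing columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$marker)) .stopf("duplicated marker entries in panel")
  if (any(df$threshold <= 0)) .stopf("marker thresholds must be > 0")
  if (sum(df$endocrine) < 2) .stopf("panel must declare at least 2 endocrine types")
  df <- df[, need]
  class(df) <- c("marker_panel", "data.frame")
  df
}

#' Read / write a marker panel as YAML
#'
#' The YAML layout is a list of entries with fields `marker`, `threshold`,
#' `cell_type`, `endocrine`.
#'
#' @param path File path.
#' @return `read_marker_panel()` returns a validated panel;
#'   `write_marker_panel()` returns `path` invisibly.
#' @export
read_marker_panel <- function(path) {
  raw <- yaml::read_yaml(path)
  df <- do.call(rbind, lapply(raw, function(e) {
    data.frame(marker = e$marker, threshold = as.numeric(e$threshold),
               cell_type = e$cell_type, endocrine = isTRUE(e$endocrine),
               stringsAsFactors = FALSE)
  }))
  marker_panel(df)
}

#' @rdname read_marker_panel
#' @param panel A `marker_panel`.
#' @export
write_marker_panel <- function(panel, path) {
  entries <- lapply(seq_len(nrow(panel)), function(i) {
    list(marker = panel$marker[i], threshold = panel$threshold[i],
         cell_type = panel$cell_type[i], endocrine = panel$endocrine[i])
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}

# type -> endocrine lookup from a panel
.endocrine_types <- function(panel) panel$cell_type[panel$endocrine]
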