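#' Remnant volumetry by parcellation-mask intersection
#'
#' For each labelled region, counts the voxels falling inside the resection
#' mask: `resected + remnant = total` holds exactly by voxel-count
#' arithmetic, and resection voxels over background (label 0) are reported
#' as unassigned rather than dropped, so volumes are conserved globally
#' too. Rows are ordered by percent resected, descending (ties by label).
#' Inputs must be pre-aligned: geometry equality is verified and any
#' mismatch fails loudly (registration is out of scope).
#'
#' @param parc A [parcellation()].
#' @param resection A `binary_mask` on the same geometry.
#' @return A `remnant_report`: list with `rows` (data frame: `label`,
#'   `region_name`, `total_ml`, `resected_ml`, `remnant_ml`,
#'   `pct_resected`), `total_resection_ml` and `unassigned_resection_ml`.
#' @export
intersect_parcellation <- function(parc, resection) {
  stopifnot(inherits(parc, "parcellation"), is_binary_mask(resection))
  if (!all(dim(parc$data) == dim(resection$data)) ||
      max(abs(parc$spacing - resection$spacing)) > 1e-5)
    stop("parcellation and resection mask must share geometry")
  labs <- sort(as.integer(names(parc$labels)))
  if (length(labs) == 0 || sum(parc$data > 0) == 0)
    stop("parcellation is empty")
  vv <- voxel_volume_ml(parc)
  nmax <- max(labs)
  total_cnt <- tabulate(parc$data[parc$data > 0], nbins = nmax)
  inside <- parc$data[resection$data == 1]
  res_cnt <- tabulate(inside[inside > 0], nbins = nmax)
  unassigned <- sum(resection$data == 1 & parc$data == 0)
  rows <- data.frame(
    label = labs,
    region_name = unname(parc$labels[as.character(labs)]),
    total_ml = total_cnt[labs] * vv,
    resected_ml = res_cnt[labs] * vv,
    # defined as the difference so conservation holds exactly in floats
    remnant_ml = total_cnt[labs] * vv - res_cnt[labs] * vv,
    pct_resected = ifelse(total_cnt[labs] > 0,
                          100 * res_cnt[labs] / total_cnt[labs], 0),
    stringsAsFactors = FALSE)
  rows <- rows[order(-rows$pct_resected, rows$label), ]
  rownames(rows) <- NULL
  structure(list(rows = rows,
                 total_resection_ml = sum(resection$data) * vv,
                 unassigned_resection_ml = unassigned * vv),
            class = "remnant_report")
}

#' Look up one region's remnant volume
#'
#' @param report A `remnant_report`.
#' @param region_name Region name present in the report.
#' @return List with `remnant_ml` and `pct_resected`.
#' @export
region_remnant <- function(report, region_name) {
  stopifnot(inherits(report, "remnant_report"))
  i <- match(region_name, report$rows$region_name)
  if (is.na(i))
    stop("unknown region '", region_name, "'; available: ",
         paste(report$rows$region_name, collapse = ", "))
  list(remnant_ml = report$rows$remnant_ml[i],
       pct_resected = report$rows$pct_resected[i])
}

#' Compare remnant estimates from manual vs predicted masks
#'
#' Both arms are mask-intersection estimates (no voxel-wise remnant ground
#' truth exists): per subject and region, the percent resected under the
#' manual and the predicted resection mask, with Pearson correlation and
#' mean absolute error (percentage points) across the series.
#'
#' @param parc A [parcellation()] or list of them (one per subject).
#' @param manual_mask,predicted_mask `binary_mask` or matching lists.
#' @param region_names Regions to compare; default `"hippocampus"`.
#' @return List with `table` (subject, region, pct_manual, pct_predicted)
#'   and `stats` (`pearson_r`, `mae_pct`, `n`).
#' @export
compare_remnant_estimates <- function(parc, manual_mask, predicted_mask,
                                      region_names = "hippocampus") {
  aslist <- function(x, cls) if (inherits(x, cls)) list(x) else x
  parc <- aslist(parc, "parcellation")
  manual_mask <- aslist(manual_mask, "binary_mask")
  predicted_mask <- aslist(predicted_mask, "binary_mask")
  n <- length(parc)
  stopifnot(length(manual_mask) == n, length(predicted_mask) == n)
  rows <- list()
  for (s in seq_len(n)) {
    rm <- intersect_parcellation(parc[[s]], manual_mask[[s]])
    rp <- intersect_parcellation(parc[[s]], predicted_mask[[s]])
    for (reg in region_names) {
      rows[[length(rows) + 1]] <- data.frame(
        subject = s, region = reg,
        pct_manual = region_remnant(rm, reg)$pct_resected,
        pct_predicted = region_remnant(rp, reg)$pct_resected,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  diffs <- tab$pct_predicted - tab$pct_manual
  r <- if (nrow(tab) >= 2 && sd(tab$pct_manual) > 0 && sd(tab$pct_predicted) > 0)
    cor(tab$pct_manual, tab$pct_predicted) else NA_real_
  list(table = tab,
       stats = list(pearson_r = r, mae_pct = mean(abs(diffs)), n = nrow(tab)))
}

#' Render a remnant report to CSV, JSON or a standalone HTML table
#'
#' CSV and JSON carry all fields at full precision; HTML shows percentages
#' to one decimal place in report order.
#'
#' @param report A `remnant_report`.
#' @param path Output file path.
#' @param format `"csv"`, `"json"` or `"html"`.
#' @return `path`, invisibly.
#' @export
render_report <- function(report, path, format = c("csv", "json", "html")) {
  stopifnot(inherits(report, "remnant_report"))
  format <- match.arg(format)
  if (format == "csv") {
    write.csv(report$rows, path, row.names = FALSE)
  } else if (format == "json") {
    jsonlite::write_json(
      list(total_resection_ml = report$total_resection_ml,
           unassigned_resection_ml = report$unassigned_resection_ml,
           regions = report$rows),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    hdr <- paste0("<tr>", paste0("<th>", c("Region", "Total (ml)",
                                           "Resected (ml)", "Remnant (ml)",
                                           "% resected"), "</th>",
                                 collapse = ""), "</tr>")
    body <- apply(report$rows, 1, function(r) {
      sprintf("<tr><td>%s</td><td>%.2f</td><td>%.2f</td><td>%.2f</td><td>%.1f</td></tr>",
              r[["region_name"]], as.numeric(r[["total_ml"]]),
              as.numeric(r[["resected_ml"]]), as.numeric(r[["remnant_ml"]]),
              as.numeric(r[["pct_resected"]]))
    })
    html <- c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
              "<title>Resection report</title></head><body>",
              sprintf("<p>Total resection volume: %.2f ml (unassigned %.2f ml)</p>",
                      report$total_resection_ml,
                      report$unassigned_resection_ml),
              "<table border='1'>", hdr, body, "</table></body></html>")
    writeLines(html, path)
  }
  invisible(path)
}

#' @export
print.remnant_report <- function(x, ...) {
  cat(sprintf("<remnant_report> total resection %.2f ml (%.2f ml unassigned)\n",
              x$total_resection_ml, x$unassigned_resection_ml))
  print(utils::head(x$rows, 10))
  invisible(x)
}
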