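toy_parc <- function() {
  lab <- array(0L, c(12, 12, 6))
  lab[1:10, 1:10, 2:3] <- 1L   # region A: 200 voxels
  lab[1:10, 1:10, 4:5] <- 2L   # region B: 200 voxels
  lab[11, 1:5, 2] <- 3L        # region C: 5 voxels
  parcellation(lab, c("1" = "hippocampus", "2" = "temporal_pole",
                      "3" = "amygdala"))
}

test_that("parcellation-mask intersection counts and conserves volumes", {
  parc <- toy_parc()
  res <- array(0, c(12, 12, 6))
  res[1:10, 1:4, 2:3] <- 1       # 80 of region 1 (of 200 total)
  res[12, 12, 1] <- 1            # 1 voxel on background
  report <- intersect_parcellation(parc, binary_mask(res))
  rows <- report$rows
  r1 <- rows[rows$label == 1, ]
  expect_equal(r1$pct_resected, 40)
  expect_equal(r1$resected_ml, 0.08)
  expect_equal(r1$remnant_ml, 0.12)
  # zero-overlap regions are present with pct 0
  expect_equal(rows$pct_resected[rows$label == 2], 0)
  # ordering: by percent resected, descending
  expect_equal(rows$pct_resected, sort(rows$pct_resected, decreasing = TRUE))
  # conservation, exactly
  expect_identical(rows$resected_ml + rows$remnant_ml, rows$total_ml)
  expect_equal(sum(rows$resected_ml) + report$unassigned_resection_ml,
               report$total_resection_ml)
  expect_equal(report$unassigned_resection_ml, 0.001)
})

test_that("degenerate resections and full resections report cleanly", {
  parc <- toy_parc()
  empty <- binary_mask(array(0, c(12, 12, 6)))
  rep0 <- intersect_parcellation(parc, empty)
  expect_true(all(rep0$rows$pct_resected == 0))
  expect_equal(rep0$total_resection_ml, 0)
  full <- array(0, c(12, 12, 6)); full[11, 1:5, 2] <- 1
  rep1 <- intersect_parcellation(parc, binary_mask(full))
  r3 <- rep1$rows[rep1$rows$label == 3, ]
  expect_equal(r3$pct_resected, 100)
  expect_equal(r3$remnant_ml, 0)
  expect_error(intersect_parcellation(parc,
                                      binary_mask(array(0, c(4, 4, 4)))),
               "share geometry")
})

test_that("reports are invariant under label renumbering", {
  parc <- toy_parc()
  res <- array(0, c(12, 12, 6)); res[1:10, 1:4, 2:3] <- 1
  rep_a <- intersect_parcellation(parc, binary_mask(res))
  relab <- parc$data
  relab[parc$data == 1L] <- 7L
  relab[parc$data == 2L] <- 5L
  parc_b <- parcellation(relab, c("7" = "hippocampus", "5" = "temporal_pole",
                                  "3" = "amygdala"))
  rep_b <- intersect_parcellation(parc_b, binary_mask(res))
  cols <- c("region_name", "total_ml", "resected_ml", "remnant_ml",
            "pct_resected")
  expect_equal(rep_a$rows[order(rep_a$rows$region_name), cols],
               rep_b$rows[order(rep_b$rows$region_name), cols],
               ignore_attr = TRUE)
})

test_that("region lookup returns the row or a helpful error", {
  parc <- toy_parc()
  res <- array(0, c(12, 12, 6)); res[1:10, 1:4, 2:3] <- 1
  report <- intersect_parcellation(parc, binary_mask(res))
  hip <- region_remnant(report, "hippocampus")
  expect_equal(hip$pct_resected, 40)
  expect_equal(hip$remnant_ml, 0.6 * 0.2)
  spared <- region_remnant(report, "temporal_pole")
  expect_equal(spared$pct_resected, 0)
  expect_equal(spared$remnant_ml, 0.2)
  expect_error(region_remnant(report, "hipocampus"), "available")
})

test_that("remnant estimate comparison recovers constructed offsets", {
  parc <- toy_parc()
  manual <- list(); predicted <- list(); parcs <- list()
  for (s in 1:3) {
    m <- array(0, c(12, 12, 6))
    m[1:10, seq_len(2 + s), 2:3] <- 1    # manual resects (2+s)*20 voxels
    p <- array(0, c(12, 12, 6))
    p[1:10, seq_len(1 + s), 2:3] <- 1    # predicted resects one column fewer
    manual[[s]] <- binary_mask(m)
    predicted[[s]] <- binary_mask(p)
    parcs[[s]] <- parc
  }
  cmp <- compare_remnant_estimates(parcs, manual, predicted)
  # each column is 20 of 200 voxels = 10 percentage points
  expect_equal(cmp$stats$mae_pct, 10)
  expect_equal(cmp$stats$pearson_r, 1)
  # identical masks: MAE exactly 0
  same <- compare_remnant_estimates(parc, manual[[1]], manual[[1]])
  expect_equal(same$stats$mae_pct, 0)
  # disjoint prediction contributes its full percentage to the error
  off <- array(0, c(12, 12, 6)); off[1:10, 1:10, 4:5] <- 1
  dis <- compare_remnant_estimates(parc, manual[[1]], binary_mask(off))
  expect_equal(dis$stats$mae_pct,
               region_remnant(intersect_parcellation(parc, manual[[1]]),
                              "hippocampus")$pct_resected)
})

test_that("rendered reports round-trip their contents", {
  parc <- toy_parc()
  res <- array(0, c(12, 12, 6)); res[1:10, 1:4, 2:3] <- 1
  report <- intersect_parcellation(parc, binary_mask(res))
  csv <- tempfile(fileext = ".csv")
  render_report(report, csv, "csv")
  back <- read.csv(csv)
  expect_equal(back$region_name, report$rows$region_name)
  expect_equal(back$pct_resected, report$rows$pct_resected)
  js <- tempfile(fileext = ".json")
  render_report(report, js, "json")
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$total_resection_ml, report$total_resection_ml)
  expect_equal(parsed$unassigned_resection_ml,
               report$unassigned_resection_ml)
  expect_equal(nrow(parsed$regions), nrow(report$rows))
  ht <- tempfile(fileext = ".html")
  render_report(report, ht, "html")
  html <- paste(readLines(ht), collapse = "\n")
  expect_equal(lengths(regmatches(html, gregexpr("<tr><td>", html))),
               nrow(report$rows))
  expect_error(render_report(report, tempfile(), "pdf"), "should be one of")
})
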