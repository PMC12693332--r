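## Bullseye rendering and clinical report assembly. The serialized plot
## data (segment -> value, (slice, chord) -> value) is the testable
## artifact; the PNG rendering is generated from it.

bullseyePalette <- function(n = 256) grDevices::hcl.colors(n, "viridis")

valueColor <- function(v, lo, hi, palette = bullseyePalette()) {
  v <- pmin(pmax(v, lo), hi)
  palette[1L + as.integer(round((v - lo) / (hi - lo) * (length(palette) - 1L)))]
}

drawAnnularSector <- function(r0, r1, a0, a1, col, border = "grey30") {
  t1 <- seq(a0, a1, length.out = 48) * pi / 180
  t2 <- rev(t1)
  graphics::polygon(c(r1 * cos(t1), r0 * cos(t2)), c(r1 * sin(t1), r0 * sin(t2)),
                    col = col, border = border, lwd = 0.4)
}

#' Render the AHA 16-segment infarct-size bullseye
#'
#' Three concentric rings (base outer, mid middle, apex inner) colored by
#' per-segment scar extent (0-100 %), numeric labels per sector, missing
#' segments hatched gray. The serialized plot data (`segment` -> `percent`)
#' round-trips exactly and is the source of truth for tests.
#'
#' @param extents a [SegmentExtent-class].
#' @param file optional PNG path; when `NULL` nothing is drawn.
#' @param anteriorAngleDeg angle at which segment 1 starts (display
#'   rotation only).
#' @return list with `data` (data.frame segment, level, percent) and
#'   `file`.
#' @export
renderBullseye16 <- function(extents, file = NULL, anteriorAngleDeg = 60) {
  e <- extents@extents
  dat <- e[, c("segment", "level", "percent")]
  if (!is.null(file)) {
    grDevices::png(file, width = 640, height = 640)
    op <- graphics::par(mar = c(1, 1, 2, 1))
    on.exit({ graphics::par(op); grDevices::dev.off() })
    graphics::plot.new()
    graphics::plot.window(c(-1.15, 1.15), c(-1.15, 1.15), asp = 1)
    rings <- list(base = c(2 / 3, 1), mid = c(1 / 3, 2 / 3), apex = c(0, 1 / 3))
    for (i in seq_len(nrow(e))) {
      lev <- e$level[i]
      nSeg <- if (lev == "apex") 4L else 6L
      segIdx <- e$segment[i] - c(base = 0L, mid = 6L, apex = 12L)[[lev]]
      a0 <- anteriorAngleDeg + (segIdx - 1L) * 360 / nSeg
      a1 <- a0 + 360 / nSeg
      col <- if (is.na(e$percent[i])) "grey85" else valueColor(e$percent[i], 0, 100)
      drawAnnularSector(rings[[lev]][1], rings[[lev]][2], a0, a1, col)
      rmid <- mean(rings[[lev]]); amid <- (a0 + a1) / 2 * pi / 180
      lab <- if (is.na(e$percent[i])) "-" else sprintf("%.0f", e$percent[i])
      graphics::text(rmid * cos(amid), rmid * sin(amid), lab, cex = 0.9,
                     col = "white")
    }
    graphics::text(0, 1.1, "Scar extent per AHA segment (%)", cex = 1.1)
  }
  list(data = dat, file = file)
}

#' Render the 100-chord transmurality bullseye
#'
#' One ring per quantified slice (apex innermost), 100 angular bins per
#' ring colored by chord transmurality in [0, 1]. The serialized data
#' (`slice`, `chord` -> `transmurality`) round-trips exactly.
#'
#' @param profile a [TransmuralityProfile-class].
#' @param file optional PNG path.
#' @param basalOutermost if `TRUE` the lowest slice index is drawn
#'   outermost.
#' @return list with `data` (data.frame slice, chord, transmurality) and
#'   `file`.
#' @export
renderBullseyeChords <- function(profile, file = NULL, basalOutermost = TRUE) {
  v <- profile@values
  dat <- v[, c("slice", "chord", "transmurality")]
  if (!is.null(file)) {
    slices <- sort(unique(v$slice))
    ns <- length(slices)
    grDevices::png(file, width = 640, height = 640)
    op <- graphics::par(mar = c(1, 1, 2, 1))
    on.exit({ graphics::par(op); grDevices::dev.off() })
    graphics::plot.new()
    graphics::plot.window(c(-1.15, 1.15), c(-1.15, 1.15), asp = 1)
    for (si in seq_along(slices)) {
      ringIdx <- if (basalOutermost) ns - si + 1L else si
      r0 <- (ringIdx - 1L) / ns; r1 <- ringIdx / ns
      vs <- v[v$slice == slices[si], ]
      vs <- vs[order(vs$chord), ]
      for (j in seq_len(nrow(vs))) {
        a0 <- vs$angleDeg[j] - 180 / nrow(vs)
        a1 <- vs$angleDeg[j] + 180 / nrow(vs)
        drawAnnularSector(r0, r1, a0, a1,
                          valueColor(vs$transmurality[j], 0, 1), border = NA)
      }
    }
    graphics::text(0, 1.1, "Chord transmurality (0-1)", cex = 1.1)
  }
  list(data = dat, file = file)
}

metricsAsList <- function(m) {
  list(myocardial_volume_ml = m@myocardialVolumeMl,
       scar_volume_ml = m@scarVolumeMl,
       scar_mass_g = m@scarMassG,
       scar_extent_percent = m@scarExtentPercent,
       mean_transmurality = m@meanTransmurality,
       max_transmurality = m@maxTransmurality,
       density_g_per_cm3 = m@densityGPerCm3,
       segment_extents = m@segmentExtents@extents)
}

metricsFromList <- function(x) {
  e <- as.data.frame(x$segment_extents)
  e$percent <- as.numeric(e$percent)
  new("ScarMetrics",
      myocardialVolumeMl = x$myocardial_volume_ml,
      scarVolumeMl = x$scar_volume_ml,
      scarMassG = x$scar_mass_g,
      scarExtentPercent = x$scar_extent_percent,
      meanTransmurality = x$mean_transmurality,
      maxTransmurality = x$max_transmurality,
      densityGPerCm3 = x$density_g_per_cm3,
      segmentExtents = new("SegmentExtent", extents = e))
}

#' Generate the clinical report
#'
#' Writes `report.json` (the single source of truth: patient meta, all
#' scar metrics, per-segment table, serialized bullseye data, method
#' provenance, timestamp) and a self-contained `report.html` generated
#' from the JSON, with both bullseye images embedded. No metric is
#' recomputed at render time.
#'
#' @param meta named list of free-form patient fields (default anonymized).
#' @param metrics a [ScarMetrics-class].
#' @param outDir output directory.
#' @param provenance named list describing the detection method and
#'   parameters.
#' @param bullseye16,bullseyeChords results of [renderBullseye16()] /
#'   [renderBullseyeChords()]; rendered here into `outDir` when given as
#'   [SegmentExtent-class] / [TransmuralityProfile-class].
#' @param timestamp report creation time string; fix it for byte-identical
#'   reruns.
#' @return invisible list with paths `json` and `html`.
#' @export
generateReport <- function(metrics, outDir,
                           meta = list(patient_id = "anonymous", study_date = ""),
                           provenance = list(),
                           bullseye16 = NULL, bullseyeChords = NULL,
                           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (is(bullseye16, "SegmentExtent"))
    bullseye16 <- renderBullseye16(bullseye16, file.path(outDir, "bullseye16.png"))
  if (is(bullseyeChords, "TransmuralityProfile"))
    bullseyeChords <- renderBullseyeChords(bullseyeChords, file.path(outDir, "bullseye_chords.png"))
  doc <- list(
    patient = meta,
    created = timestamp,
    provenance = c(list(software = "ScarQuant",
                        version = as.character(utils::packageVersion("ScarQuant"))),
                   provenance),
    metrics = metricsAsList(metrics),
    bullseye16 = if (!is.null(bullseye16)) bullseye16$data,
    bullseye_chords = if (!is.null(bullseyeChords)) bullseyeChords$data)
  jsonPath <- file.path(outDir, "report.json")
  jsonlite::write_json(doc, jsonPath, auto_unbox = TRUE, digits = NA, null = "null")
  htmlPath <- file.path(outDir, "report.html")
  writeReportHtml(doc, htmlPath,
                  img16 = if (!is.null(bullseye16)) bullseye16$file,
                  imgCh = if (!is.null(bullseyeChords)) bullseyeChords$file)
  invisible(list(json = jsonPath, html = htmlPath))
}

embedImage <- function(path) {
  if (is.null(path) || !file.exists(path)) return("")
  b64 <- jsonlite::base64_enc(readBin(path, "raw", file.info(path)$size))
  sprintf('<img src="data:image/png;base64,%s" width="420"/>', gsub("\n", "", b64))
}

writeReportHtml <- function(doc, path, img16 = NULL, imgCh = NULL) {
  m <- doc$metrics
  segRows <- paste(apply(m$segment_extents, 1, function(r)
    sprintf("<tr><td>%s</td><td>%s</td><td>%s</td><td>%s</td><td>%s</td></tr>",
            r[["segment"]], r[["level"]], r[["scarPx"]], r[["totalPx"]],
            ifelse(is.na(r[["percent"]]), "missing",
                   sprintf("%.1f", as.numeric(r[["percent"]]))))), collapse = "\n")
  html <- sprintf(
'<!DOCTYPE html><html><head><meta charset="utf-8"/>
<title>Myocardial scar quantification report</title>
<style>body{font-family:sans-serif;margin:2em}table{border-collapse:collapse}
td,th{border:1px solid #999;padding:2px 8px}</style></head><body>
<h1>Myocardial scar quantification report</h1>
<p>Patient: %s &nbsp; Study date: %s &nbsp; Created: %s</p>
<h2>Global metrics</h2>
<table>
<tr><th>Myocardial volume</th><td>%.2f mL</td></tr>
<tr><th>Scar volume</th><td>%.2f mL</td></tr>
<tr><th>Scar mass</th><td>%.2f g (density %.2f g/cm&sup3;)</td></tr>
<tr><th>Scar extent</th><td>%.1f %%</td></tr>
<tr><th>Mean transmurality</th><td>%.3f</td></tr>
<tr><th>Max transmurality</th><td>%.3f</td></tr>
</table>
<h2>Bullseye plots</h2>
%s %s
<h2>Per-segment extent</h2>
<table><tr><th>Segment</th><th>Level</th><th>Scar px</th><th>Total px</th><th>Percent</th></tr>
%s
</table>
<h2>Provenance</h2><pre>%s</pre>
</body></html>',
    doc$patient$patient_id, doc$patient$study_date, doc$created,
    m$myocardial_volume_ml, m$scar_volume_ml, m$scar_mass_g, m$density_g_per_cm3,
    m$scar_extent_percent, m$mean_transmurality, m$max_transmurality,
    embedImage(img16), embedImage(imgCh), segRows,
    jsonlite::toJSON(doc$provenance, auto_unbox = TRUE, pretty = TRUE))
  writeLines(html, path)
  invisible(path)
}
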