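# Figure rendering: one polyline per sample over window midpoints, per
# chromosome or genome-wide. A single figure description feeds both the
# interactive HTML renderer (self-contained SVG with native browser
# tooltips and a JS legend toggle) and the static ggplot2 renderer
# (PDF/SVG/PNG), so trace counts and data arrays are identical across
# formats.

# Fixed 12-color colorblind-safe categorical cycle (Tol muted + extras),
# recycled with a warning beyond 12 groups.
.categoricalPalette <- c(
  "#332288", "#88CCEE", "#44AA99", "#117733", "#999933", "#DDCC77",
  "#CC6677", "#882255", "#AA4499", "#DDDDDD", "#6699CC", "#661100"
)

# Min-max scale a quantitative column to [0, 1]; constant columns map to 0.5.
.minMaxScale <- function(x) {
  rng <- range(x, na.rm = TRUE)
  if (!is.finite(rng[1]) || rng[2] == rng[1]) {
    return(ifelse(is.na(x), NA_real_, 0.5))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

.continuousColor <- function(u) {
  pal <- grDevices::colorRamp(grDevices::hcl.colors(256, "viridis"))
  out <- rep("#888888", length(u))
  ok <- !is.na(u)
  if (any(ok)) {
    rgb <- pal(u[ok])
    out[ok] <- grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
  }
  out
}

# Assign one color per sample from metadata: categorical column -> palette
# cycle per group; numeric column -> continuous spectrum after min-max
# scaling; no metadata/column -> monochrome.
.sampleColors <- function(sampleIds, meta, colorBy) {
  if (is.null(meta) || is.null(colorBy)) {
    return(list(color = rep("#444444", length(sampleIds)),
                group = rep("all", length(sampleIds)),
                continuous = FALSE, position = rep(NA_real_, length(sampleIds))))
  }
  if (!colorBy %in% colnames(meta)) {
    stop("unknown color-by column '", colorBy, "'; available: ",
         paste(setdiff(colnames(meta), "sample"), collapse = ", "),
         call. = FALSE)
  }
  vals <- meta[match(sampleIds, meta$sample), colorBy]
  if (is.numeric(vals)) {
    u <- .minMaxScale(vals)
    list(color = .continuousColor(u), group = rep("all", length(sampleIds)),
         continuous = TRUE, position = u)
  } else {
    vals <- as.character(vals)
    vals[is.na(vals)] <- "NA"
    groups <- unique(vals)
    if (length(groups) > length(.categoricalPalette)) {
      warning("more than ", length(.categoricalPalette),
              " groups; recycling the categorical palette", call. = FALSE)
    }
    gi <- match(vals, groups)
    pal <- rep_len(.categoricalPalette, length(groups))
    list(color = pal[gi], group = vals, continuous = FALSE,
         position = rep(NA_real_, length(sampleIds)))
  }
}

.hoverText <- function(sampleId, meta) {
  if (is.null(meta)) return(sampleId)
  row <- meta[match(sampleId, meta$sample), , drop = FALSE]
  cols <- setdiff(colnames(row), "sample")
  if (!length(cols)) return(sampleId)
  paste0(sampleId, "; ",
         paste(cols, vapply(cols, function(cc) as.character(row[[cc]]),
                            character(1)),
               sep = "=", collapse = "; "))
}

#' Build a figure description from PC tracks
#'
#' The figure description is the single source for every output format:
#' a list of per-sample traces (x = window midpoints with per-chromosome
#' offsets, y = polarized scores, `NA` at invalid windows), per-sample
#' colors and hover text, and chromosome panel boundaries.
#'
#' @param tracks list of [PCTrack-class] objects (one per chromosome,
#'   plotted left to right in input order).
#' @param meta optional sample metadata from [readSampleMetadata()].
#' @param pc PC index to plot.
#' @param colorBy metadata column for coloring (categorical or numeric).
#' @param groupOrder optional explicit group plotting order (z-stacking).
#' @param interval optional `c(start, end)` bp restriction (single track).
#' @return a `pcFigure` list: `traces`, `panels`, `pc`, `continuous`.
#' @export
buildFigure <- function(tracks, meta = NULL, pc = 1L, colorBy = NULL,
                        groupOrder = NULL, interval = NULL) {
  if (inherits(tracks, "PCTrack")) tracks <- list(tracks)
  if (!length(tracks)) stop("no tracks to plot", call. = FALSE)
  sampleIds <- colnames(tracks[[1]])
  for (t in tracks[-1]) {
    if (!setequal(colnames(t), sampleIds)) {
      first <- c(setdiff(colnames(t), sampleIds),
                 setdiff(sampleIds, colnames(t)))[1]
      stop("inconsistent sample sets across tracks (first discrepancy: '",
           first, "')", call. = FALSE)
    }
  }
  if (!is.null(interval) && length(tracks) == 1L) {
    mids <- windowMids(tracks[[1]])
    keep <- mids >= interval[1] & mids <= interval[2]
    if (!any(keep)) stop("plot interval contains no windows", call. = FALSE)
    tracks[[1]] <- tracks[[1]][keep, ]
  }
  anyValid <- any(vapply(tracks, function(t) any(validWindows(t)), logical(1)))
  if (!anyValid) stop("no valid windows to plot", call. = FALSE)
  col <- .sampleColors(sampleIds, meta, colorBy)
  offset <- 0
  xs <- list()
  panels <- data.frame(chrom = character(), xmin = numeric(),
                       xmax = numeric())
  ys <- lapply(tracks, function(t) pcScores(t, pc))
  for (i in seq_along(tracks)) {
    t <- tracks[[i]]
    mids <- windowMids(t)
    span <- max(end(rowRanges(t)))
    xs[[i]] <- mids + offset
    panels <- rbind(panels, data.frame(
      chrom = chromName(t), xmin = offset + 1, xmax = offset + span
    ))
    offset <- offset + span
  }
  traces <- lapply(seq_along(sampleIds), function(s) {
    id <- sampleIds[s]
    y <- unlist(lapply(seq_along(tracks), function(i) {
      ys[[i]][, match(id, colnames(tracks[[i]]))]
    }), use.names = FALSE)
    list(
      sample = id, x = unlist(xs, use.names = FALSE), y = y,
      color = col$color[s], group = col$group[s],
      hover = .hoverText(id, meta)
    )
  })
  # draw order: user group order (or first-appearance order), then input order
  groups <- unique(col$group)
  if (!is.null(groupOrder)) {
    groups <- c(intersect(groupOrder, groups), setdiff(groups, groupOrder))
  }
  ord <- order(match(col$group, groups), seq_along(sampleIds))
  traces <- traces[ord]
  structure(
    list(traces = traces, panels = panels, pc = as.integer(pc),
         continuous = col$continuous),
    class = "pcFigure"
  )
}

# Split a trace into contiguous non-NA runs: an NA window must render as a
# visible gap, never an interpolated segment.
.traceRuns <- function(y) {
  ok <- !is.na(y)
  runs <- rle(ok)
  endIdx <- cumsum(runs$lengths)
  startIdx <- endIdx - runs$lengths + 1L
  Map(function(a, b) a:b, startIdx[runs$values], endIdx[runs$values])
}

.renderFigureHTML <- function(fig, path, width = 1400, height = 500) {
  padL <- 70; padR <- 20; padT <- 30; padB <- 50
  allX <- unlist(lapply(fig$traces, `[[`, "x"))
  allY <- unlist(lapply(fig$traces, `[[`, "y"))
  xr <- range(allX, na.rm = TRUE)
  yr <- range(allY, na.rm = TRUE)
  if (!is.finite(yr[1])) yr <- c(-1, 1)
  if (yr[1] == yr[2]) yr <- yr + c(-1, 1)
  sx <- function(x) padL + (x - xr[1]) / max(1, diff(xr)) * (width - padL - padR)
  sy <- function(y) padT + (yr[2] - y) / diff(yr) * (height - padT - padB)
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  parts <- c(sprintf(
    '<svg id="pcscan" xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
    width, height, width, height
  ))
  for (i in seq_len(nrow(fig$panels))) {
    xb <- sx(fig$panels$xmax[i])
    parts <- c(parts,
      sprintf('<line x1="%.1f" y1="%d" x2="%.1f" y2="%d" stroke="#bbbbbb" stroke-dasharray="4 3"/>',
              xb, padT, xb, height - padB),
      sprintf('<text x="%.1f" y="%d" text-anchor="middle" font-size="12">%s</text>',
              (sx(fig$panels$xmin[i]) + xb) / 2, height - padB + 20,
              esc(fig$panels$chrom[i]))
    )
  }
  zero <- sy(0)
  if (zero >= padT && zero <= height - padB) {
    parts <- c(parts, sprintf(
      '<line x1="%d" y1="%.1f" x2="%d" y2="%.1f" stroke="#dddddd"/>',
      padL, zero, width - padR, zero
    ))
  }
  parts <- c(parts, sprintf(
    '<text x="15" y="%.1f" transform="rotate(-90 15 %.1f)" text-anchor="middle" font-size="12">PC%d</text>',
    height / 2, height / 2, fig$pc
  ))
  for (tr in fig$traces) {
    parts <- c(parts, sprintf(
      '<g class="trace" data-sample="%s" data-group="%s" stroke="%s" fill="none">',
      esc(tr$sample), esc(tr$group), tr$color
    ))
    for (run in .traceRuns(tr$y)) {
      pts <- paste(sprintf("%.1f,%.1f", sx(tr$x[run]), sy(tr$y[run])),
                   collapse = " ")
      if (length(run) == 1L) {
        parts <- c(parts, sprintf(
          '<circle cx="%.1f" cy="%.1f" r="2" fill="%s" stroke="none"><title>%s</title></circle>',
          sx(tr$x[run]), sy(tr$y[run]), tr$color, esc(tr$hover)
        ))
      } else {
        parts <- c(parts, sprintf(
          '<polyline points="%s" stroke-width="1.2"><title>%s</title></polyline>',
          pts, esc(tr$hover)
        ))
      }
    }
    parts <- c(parts, "</g>")
  }
  parts <- c(parts, "</svg>")
  groups <- unique(vapply(fig$traces, `[[`, character(1), "group"))
  legend <- if (!fig$continuous && length(groups) > 1L) {
    cols <- vapply(groups, function(g) {
      fig$traces[[match(g, vapply(fig$traces, `[[`, character(1), "group"))]]$color
    }, character(1))
    paste0(
      '<div id="legend">',
      paste(sprintf(
        '<span class="key" data-group="%s" style="cursor:pointer"><span style="color:%s">&#9632;</span> %s</span>',
        esc(groups), cols, esc(groups)
      ), collapse = " &nbsp; "),
      "</div>"
    )
  } else ""
  js <- paste(
    "<script>",
    "document.querySelectorAll('#legend .key').forEach(function(k){",
    "  k.addEventListener('click', function(){",
    "    var g = k.getAttribute('data-group');",
    "    var off = k.classList.toggle('off');",
    "    k.style.opacity = off ? 0.3 : 1.0;",
    "    document.querySelectorAll('.trace').forEach(function(t){",
    "      if (t.getAttribute('data-group') === g)",
    "        t.style.display = off ? 'none' : '';",
    "    });",
    "  });",
    "});",
    "</script>", sep = "\n"
  )
  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"><title>windowed PC scan</title></head>",
    "<body>", legend, parts, js, "</body></html>"
  )
  writeLines(html, path)
  invisible(path)
}

.figureToFrame <- function(fig) {
  do.call(rbind, lapply(fig$traces, function(tr) {
    runs <- .traceRuns(tr$y)
    if (!length(runs)) return(NULL)
    do.call(rbind, lapply(seq_along(runs), function(r) {
      idx <- runs[[r]]
      data.frame(
        sample = tr$sample, segment = paste0(tr$sample, "_", r),
        x = tr$x[idx], y = tr$y[idx], color = tr$color, group = tr$group,
        stringsAsFactors = FALSE
      )
    }))
  }))
}

.renderFigureStatic <- function(fig, path, width = 1400, height = 500) {
  df <- .figureToFrame(fig)
  colMap <- unique(df[, c("sample", "color")])
  pal <- stats::setNames(colMap$color, colMap$sample)
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$x, y = .data$y, group = .data$segment, colour = .data$sample
  )) +
    ggplot2::geom_vline(xintercept = fig$panels$xmax, linetype = "dashed",
                        colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_line(linewidth = 0.35) +
    ggplot2::scale_colour_manual(values = pal, guide = "none") +
    ggplot2::scale_x_continuous(
      breaks = (fig$panels$xmin + fig$panels$xmax) / 2,
      labels = fig$panels$chrom
    ) +
    ggplot2::labs(x = NULL, y = paste0("PC", fig$pc)) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, width = width / 100, height = height / 100,
                  dpi = 100, units = "in")
  invisible(path)
}

.renderFigure <- function(fig, out, width = 1400, height = 500) {
  for (path in out) {
    ext <- tolower(tools::file_ext(path))
    if (ext == "html") {
      .renderFigureHTML(fig, path, width, height)
    } else if (ext %in% c("pdf", "svg", "png")) {
      .renderFigureStatic(fig, path, width, height)
    } else {
      stop("unsupported output format '.", ext,
           "'; use html, pdf, svg or png", call. = FALSE)
    }
  }
  invisible(out)
}

#' Plot a polarized PC track along one chromosome
#'
#' Draws one polyline per sample over window midpoints; invalid (`NA`)
#' windows break the line into a visible gap. HTML output is a
#' self-contained interactive page (per-trace hover text carrying the
#' sample id and all metadata columns, click-to-toggle legend groups);
#' PDF/SVG/PNG outputs are rendered from the same figure description via
#' ggplot2. Categorical metadata colors samples by group from a fixed
#' 12-color colorblind-safe cycle; a numeric column colors samples along a
#' continuous spectrum after min-max scaling. Plotting never mutates track
#' files.
#'
#' @param track a polarized [PCTrack-class].
#' @param meta optional metadata from [readSampleMetadata()].
#' @param pc PC index (default 1).
#' @param colorBy metadata column name for coloring.
#' @param groupOrder optional explicit group plotting order.
#' @param interval optional `c(start, end)` bp restriction.
#' @param out character vector of output paths; format per extension
#'   (`.html`, `.pdf`, `.svg`, `.png`).
#' @param width,height output size in px (default 1400 x 500).
#' @return invisibly, the output paths.
#' @export
chromPlot <- function(track, meta = NULL, pc = 1L, colorBy = NULL,
                      groupOrder = NULL, interval = NULL,
                      out = "chromplot.html", width = 1400, height = 500) {
  fig <- buildFigure(track, meta = meta, pc = pc, colorBy = colorBy,
                     groupOrder = groupOrder, interval = interval)
  .renderFigure(fig, out, width, height)
}

#' Plot polarized PC tracks across multiple chromosomes
#'
#' Chromosomes are laid out left to right in input order on a shared score
#' axis, separated by dashed panel boundaries and labeled along the x axis.
#' Samples are aligned across tracks by id, so tracks may order their
#' columns differently. Trace and hover semantics are as in [chromPlot()].
#'
#' @param tracks list of [PCTrack-class] objects, one per chromosome.
#' @inheritParams chromPlot
#' @return invisibly, the output paths.
#' @export
genomePlot <- function(tracks, meta = NULL, pc = 1L, colorBy = NULL,
                       groupOrder = NULL, out = "genomeplot.html",
                       width = 1400, height = 500) {
  fig <- buildFigure(tracks, meta = meta, pc = pc, colorBy = colorBy,
                     groupOrder = groupOrder)
  .renderFigure(fig, out, width, height)
}

#' @importFrom ggplot2 .data
NULL
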