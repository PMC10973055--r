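# Static renderings of the three linked views (phase, instrument,
# supplementary) plus machine/human report output.
#
# Renderers are split into a "model" step (pure data: node positions, arc
# widths, bar lengths — every number taken verbatim from the aggregate
# structures, with only monotone scaling applied) and a "draw" step that puts
# the model on a graphics device. Tests inspect the model, not pixels.

#' View styling
#'
#' The color mapping is fixed across all views: red = train, green = val,
#' blue = test. Arc stroke widths scale linearly with occurrence counts
#' between `min_arc_width` and `max_arc_width` (a monotone map with a
#' positive floor, so rare transitions stay visible).
#'
#' @param set_colors named vector of colors for train/val/test.
#' @param min_arc_width,max_arc_width stroke-width range in lwd units.
#' @export
view_style <- function(set_colors = c(train = "#d62728", val = "#2ca02c",
                                      test = "#1f77b4"),
                       min_arc_width = 0.5, max_arc_width = 8) {
  stopifnot(all(.SETS %in% names(set_colors)), min_arc_width > 0,
            max_arc_width >= min_arc_width)
  structure(list(set_colors = set_colors[.SETS],
                 min_arc_width = min_arc_width,
                 max_arc_width = max_arc_width),
            class = "view_style")
}

# Linear occurrence -> stroke width map; strictly increasing in the count.
scale_arc_width <- function(counts, style) {
  m <- max(counts, 1L)
  style$min_arc_width +
    (style$max_arc_width - style$min_arc_width) * counts / m
}

.open_device <- function(file, width = 10, height = 7) {
  ext <- tolower(tools::file_ext(file))
  switch(ext,
         svg = grDevices::svg(file, width = width, height = height),
         png = grDevices::png(file, width = width * 96, height = height * 96,
                              res = 96),
         pdf = grDevices::pdf(file, width = width, height = height),
         stop("unsupported image format: .", ext))
}

# Draw an annular (donut) sector chart at (x, y); r0 = 0 gives a pie.
draw_donut <- function(x, y, r0, r1, fracs, cols, n_seg = 40L) {
  fracs <- fracs[fracs > 0]
  cols <- cols[names(fracs)]
  a <- pi / 2 - 2 * pi * c(0, cumsum(fracs) / sum(fracs))
  for (i in seq_along(fracs)) {
    th <- seq(a[i], a[i + 1L], length.out = n_seg)
    px <- c(x + r1 * cos(th), rev(x + r0 * cos(th)))
    py <- c(y + r1 * sin(th), rev(y + r0 * sin(th)))
    graphics::polygon(px, py, col = cols[i], border = "white", lwd = 0.4)
  }
}

#' Build the phase-view rendering model
#'
#' Nodes sit left to right in conceptual order; each node carries the per-set
#' frame proportions (donut), the number of surgeries containing the phase
#' (node centre), and a radius scaled by total frames. Arcs carry transition
#' occurrence counts mapped monotonically to stroke width; forward arcs go in
#' the upper half, backward arcs in the lower half, and sentinel transitions
#' enter from the left edge / exit at the right edge.
#'
#' @param phase_counts an [aggregate_phase_counts()] result.
#' @param transition_counts an [aggregate_transition_counts()] result.
#' @param instrument_phase_counts optional [per_phase_instrument_counts()]
#'   result for the per-phase instrument bars.
#' @param config a [dataset_config()].
#' @param style a [view_style()].
#' @return object of class `phase_view_model` with `nodes`, `arcs`,
#'   `phase_bar` and `instrument_bars` components.
#' @export
phase_view_model <- function(phase_counts, transition_counts,
                             instrument_phase_counts = NULL, config,
                             style = view_style()) {
  P <- length(config$phases)
  if (P == 0L) stop("empty phase vocabulary: nothing to render")
  fr <- phase_counts$frames
  wide <- tapply(fr$frames, list(fr$phase, fr$set), sum)
  wide <- wide[config$phases, .SETS, drop = FALSE]
  wide[is.na(wide)] <- 0
  total <- rowSums(wide)
  if (sum(total) == 0L) stop("no phase-labelled frames: nothing to render")
  nodes <- data.frame(phase = config$phases, x = seq_len(P),
                      train = wide[, "train"], val = wide[, "val"],
                      test = wide[, "test"], total = total,
                      surgeries = phase_counts$surgeries$n_surgeries,
                      radius = ifelse(total > 0,
                                      0.18 + 0.17 * sqrt(total / max(total)), 0),
                      stringsAsFactors = FALSE)
  rownames(nodes) <- NULL

  tc <- transition_counts
  tc$key <- transition_key(tc$source, tc$target)
  tw <- tapply(tc$count, list(tc$key, tc$set), sum)
  tw[is.na(tw)] <- 0
  meta <- unique(as.data.frame(tc[c("key", "source", "target", "direction")]))
  arcs <- data.frame(meta,
                     train = tw[meta$key, "train"], val = tw[meta$key, "val"],
                     test = tw[meta$key, "test"], stringsAsFactors = FALSE)
  arcs$total <- arcs$train + arcs$val + arcs$test
  arcs <- arcs[arcs$total > 0, , drop = FALSE]
  arcs$x0 <- ifelse(arcs$source == .START_SENTINEL, 0,
                    match(arcs$source, config$phases))
  arcs$x1 <- ifelse(arcs$target == .END_SENTINEL, P + 1,
                    match(arcs$target, config$phases))
  arcs$side <- ifelse(arcs$direction == "forward", "upper",
                      ifelse(arcs$direction == "backward", "lower", "edge"))
  arcs$width <- scale_arc_width(arcs$total, style)
  rownames(arcs) <- NULL

  instrument_bars <- NULL
  if (!is.null(instrument_phase_counts)) {
    instrument_bars <- instrument_phase_counts
  }
  structure(list(nodes = nodes, arcs = arcs,
                 phase_bar = data.frame(phase = nodes$phase, x = nodes$x,
                                        total = nodes$total,
                                        stringsAsFactors = FALSE),
                 instrument_bars = instrument_bars,
                 style = style, config = config),
            class = "phase_view_model")
}

#' Render the phase view to an image file
#'
#' @param model a [phase_view_model()], or `NULL` to build one from the other
#'   arguments.
#' @param file output path (`.svg`, `.png` or `.pdf`).
#' @param show_arc_pies overlay a per-set pie chart on each transition arc.
#' @inheritParams phase_view_model
#' @return the file path, invisibly.
#' @export
render_phase_view <- function(model = NULL, file, phase_counts = NULL,
                              transition_counts = NULL,
                              instrument_phase_counts = NULL, config = NULL,
                              style = view_style(), show_arc_pies = FALSE) {
  if (is.null(model)) {
    model <- phase_view_model(phase_counts, transition_counts,
                              instrument_phase_counts, config, style)
  }
  nodes <- model$nodes; arcs <- model$arcs; style <- model$style
  P <- nrow(nodes)
  .open_device(file, width = max(8, 1.6 * P), height = 8)
  on.exit(grDevices::dev.off())
  has_inst <- !is.null(model$instrument_bars)
  ylo <- if (has_inst) -6.5 else -4
  graphics::plot.new()
  graphics::plot.window(xlim = c(-0.6, P + 1.6), ylim = c(ylo, 4.2))
  graphics::title(main = sprintf("Phase view — %s", model$config$name))
  # arcs
  arc_xy <- function(x0, x1, sign) {
    mid <- (x0 + x1) / 2; r <- abs(x1 - x0) / 2
    th <- seq(0, pi, length.out = 60L)
    list(x = mid + r * cos(th), y = sign * 0.9 * r * sin(th))
  }
  for (i in seq_len(nrow(arcs))) {
    a <- arcs[i, ]
    sgn <- if (a$side == "lower") -1 else 1
    xy <- arc_xy(a$x0, a$x1, sgn)
    col <- if (a$side == "edge") "grey40" else "grey25"
    graphics::lines(xy$x, xy$y, lwd = a$width, col = col)
    if (isTRUE(show_arc_pies)) {
      top <- which.max(abs(xy$y))
      fr <- c(train = a$train, val = a$val, test = a$test)
      if (sum(fr) > 0) {
        draw_donut(xy$x[top], xy$y[top], 0, 0.12, fr / sum(fr),
                   style$set_colors)
      }
    }
  }
  # nodes: donut of per-set proportions, surgery count in the centre
  for (i in seq_len(P)) {
    nd <- nodes[i, ]
    fr <- c(train = nd$train, val = nd$val, test = nd$test)
    if (sum(fr) > 0) {
      draw_donut(nd$x, 0, 0.55 * nd$radius, nd$radius, fr / sum(fr),
                 style$set_colors)
    }
    graphics::text(nd$x, 0, nd$surgeries, cex = 0.8)
    graphics::text(nd$x, -1.15, nd$phase, srt = 35, adj = 1, cex = 0.75)
  }
  # per-phase totals bar chart
  bh <- 1.4 * model$phase_bar$total / max(model$phase_bar$total)
  graphics::rect(model$phase_bar$x - 0.3, -3.6, model$phase_bar$x + 0.3,
                 -3.6 + bh, col = "grey70", border = NA)
  graphics::text(0.2, -2.6, "frames/phase", srt = 90, cex = 0.7)
  # per-phase instrument bars (centred, one thin bar per instrument x set)
  if (has_inst) {
    ib <- model$instrument_bars
    m <- max(ib$frames, 1L)
    insts <- unique(ib$instrument)
    for (i in seq_len(P)) {
      ph <- nodes$phase[i]
      for (j in seq_along(insts)) {
        y <- -4.2 - 0.5 * j
        for (k in seq_along(.SETS)) {
          v <- ib$frames[ib$phase == ph & ib$instrument == insts[j] &
                           ib$set == .SETS[k]]
          if (length(v) && v > 0) {
            w <- 0.28 * v / m
            graphics::rect(nodes$x[i] - w, y + 0.12 * (k - 2) - 0.05,
                           nodes$x[i] + w, y + 0.12 * (k - 2) + 0.05,
                           col = style$set_colors[.SETS[k]], border = NA)
          }
        }
      }
    }
    graphics::text(rep(0.2, length(insts)), -4.2 - 0.5 * seq_along(insts),
                   insts, cex = 0.6, adj = 1)
  }
  graphics::legend("topright", legend = .SETS, fill = style$set_colors,
                   bty = "n", cex = 0.8)
  invisible(file)
}

#' Build the instrument-view rendering model
#'
#' Instruments (plus an idle slot) are arranged radially with per-set bars;
#' combination nodes are placed by a seeded force-directed layout and
#' rendered as per-set pie charts sized by total frames.
#'
#' @param inst_counts an [aggregate_instrument_counts()] result.
#' @param combo_counts an [aggregate_combination_counts()] result.
#' @param config a [dataset_config()].
#' @param style a [view_style()].
#' @param normalize `"global"` scales all bars by the overall maximum;
#'   `"per_instrument"` scales each instrument's bars by its own maximum
#'   (better visibility for rare instruments).
#' @param layout_seed seed for the force-directed combination-node layout.
#' @return object of class `instrument_view_model` with `bars` and `combos`.
#' @export
instrument_view_model <- function(inst_counts, combo_counts, config,
                                  style = view_style(),
                                  normalize = c("global", "per_instrument"),
                                  layout_seed = 42L) {
  normalize <- match.arg(normalize)
  labs <- c(config$instruments, "(idle)")
  K <- length(labs)
  angles <- seq(0, 2 * pi, length.out = K + 1L)[seq_len(K)] + pi / 2
  idf <- inst_counts$instruments
  wide <- tapply(idf$frames, list(idf$instrument, idf$set), sum)
  wide <- wide[config$instruments, .SETS, drop = FALSE]
  wide[is.na(wide)] <- 0
  wide <- rbind(wide, `(idle)` = stats::setNames(inst_counts$idle$frames,
                                                 inst_counts$idle$set)[.SETS])
  scale_base <- switch(normalize,
                       global = rep(max(wide, 1L), K),
                       per_instrument = pmax(apply(wide, 1L, max), 1L))
  bars <- data.frame(label = rep(labs, each = length(.SETS)),
                     angle = rep(angles, each = length(.SETS)),
                     set = rep(.SETS, times = K),
                     frames = as.integer(t(wide)),
                     length = as.numeric(t(wide / scale_base)),
                     stringsAsFactors = FALSE)

  cdf <- combo_counts$combinations
  combos <- NULL
  if (nrow(cdf)) {
    cw <- tapply(cdf$frames, list(cdf$combination, cdf$set), sum)
    cw[is.na(cw)] <- 0
    cw <- cw[, .SETS, drop = FALSE]
    keys <- rownames(cw)
    members <- strsplit(keys, "+", fixed = TRUE)
    edges <- do.call(rbind, lapply(seq_along(keys), function(i) {
      cbind(paste0("combo:", keys[i]), members[[i]])
    }))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv())
    set.seed(as.integer(layout_seed))
    xy <- igraph::layout_with_fr(g, niter = 200L)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    rownames(xy) <- igraph::V(g)$name
    # normalize combo coordinates into the inner disk (radius 0.55)
    cxy <- xy[paste0("combo:", keys), , drop = FALSE]
    rng <- max(abs(cxy), 1e-9)
    cxy <- 0.55 * cxy / rng
    total <- rowSums(cw)
    combos <- data.frame(combination = keys,
                         train = cw[, "train"], val = cw[, "val"],
                         test = cw[, "test"], total = total,
                         x = cxy[, 1L], y = cxy[, 2L],
                         radius = 0.04 + 0.08 * sqrt(total / max(total)),
                         stringsAsFactors = FALSE)
    rownames(combos) <- NULL
  }
  structure(list(bars = bars, combos = combos, style = style,
                 config = config, normalize = normalize,
                 layout_seed = as.integer(layout_seed)),
            class = "instrument_view_model")
}

#' Render the instrument view to an image file
#'
#' @param model an [instrument_view_model()], or `NULL` to build one.
#' @param file output path (`.svg`, `.png` or `.pdf`).
#' @inheritParams instrument_view_model
#' @export
render_instrument_view <- function(model = NULL, file, inst_counts = NULL,
                                   combo_counts = NULL, config = NULL,
                                   style = view_style(),
                                   normalize = "global", layout_seed = 42L) {
  if (is.null(model)) {
    model <- instrument_view_model(inst_counts, combo_counts, config, style,
                                   normalize, layout_seed)
  }
  style <- model$style
  .open_device(file, width = 8, height = 8)
  on.exit(grDevices::dev.off())
  graphics::plot.new()
  graphics::plot.window(xlim = c(-1.8, 1.8), ylim = c(-1.8, 1.8), asp = 1)
  graphics::title(main = sprintf("Instrument view — %s", model$config$name))
  th <- seq(0, 2 * pi, length.out = 120L)
  graphics::lines(0.85 * cos(th), 0.85 * sin(th), col = "grey85")
  bars <- model$bars
  off <- c(train = -0.05, val = 0, test = 0.05)
  for (i in seq_len(nrow(bars))) {
    b <- bars[i, ]
    if (b$length <= 0) next
    a <- b$angle + off[b$set]
    r0 <- 0.85; r1 <- 0.85 + 0.6 * b$length
    graphics::segments(r0 * cos(a), r0 * sin(a), r1 * cos(a), r1 * sin(a),
                       lwd = 5, col = style$set_colors[b$set], lend = 1)
  }
  for (lab in unique(bars$label)) {
    a <- bars$angle[bars$label == lab][1L]
    graphics::text(1.62 * cos(a), 1.62 * sin(a), lab, cex = 0.75)
  }
  if (!is.null(model$combos)) {
    for (i in seq_len(nrow(model$combos))) {
      cb <- model$combos[i, ]
      fr <- c(train = cb$train, val = cb$val, test = cb$test)
      draw_donut(cb$x, cb$y, 0, cb$radius, fr / sum(fr), style$set_colors)
    }
  }
  graphics::legend("topleft", legend = .SETS, fill = style$set_colors,
                   bty = "n", cex = 0.8)
  invisible(file)
}

#' Build the supplementary-view rendering model
#'
#' @param totals a [per_set_totals()] result.
#' @param durations a [surgery_durations()] result.
#' @param split the [split_assignment()].
#' @param style a [view_style()].
#' @return object of class `supplementary_model` with `totals`,
#'   `per_surgery` (ordered by set then id) and `means`.
#' @export
supplementary_model <- function(totals, durations, split,
                                style = view_style()) {
  per <- durations$per_surgery
  per <- per[order(match(per$set, .SETS), per$surgery_id), , drop = FALSE]
  per$x <- seq_len(nrow(per))
  rownames(per) <- NULL
  structure(list(totals = totals, per_surgery = per,
                 means = durations$per_set, sets_present = sets_present(split),
                 style = style),
            class = "supplementary_model")
}

#' Render the supplementary view to an image file
#'
#' Left: mirrored bar charts of the number of surgeries (up) and total frames
#' (down) per set. Right: per-surgery duration bars grouped by set with
#' dashed per-set mean lines; panels for empty sets are omitted.
#'
#' @param model a [supplementary_model()], or `NULL` to build one.
#' @param file output path (`.svg`, `.png` or `.pdf`).
#' @inheritParams supplementary_model
#' @export
render_supplementary <- function(model = NULL, file, totals = NULL,
                                 durations = NULL, split = NULL,
                                 style = view_style()) {
  if (is.null(model)) model <- supplementary_model(totals, durations, split, style)
  style <- model$style
  .open_device(file, width = 11, height = 5)
  on.exit(grDevices::dev.off())
  graphics::layout(matrix(1:2, nrow = 1L), widths = c(1, 2.2))
  tot <- model$totals[model$totals$set %in% model$sets_present, , drop = FALSE]
  # mirrored totals
  graphics::par(mar = c(3, 4, 3, 1))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0.5, nrow(tot) + 0.5), ylim = c(-1.1, 1.1))
  graphics::title(main = "Per-set totals")
  su <- tot$surgeries / max(tot$surgeries)
  fu <- tot$frames / max(tot$frames)
  for (i in seq_len(nrow(tot))) {
    col <- style$set_colors[tot$set[i]]
    graphics::rect(i - 0.3, 0, i + 0.3, su[i], col = col, border = NA)
    graphics::rect(i - 0.3, 0, i + 0.3, -fu[i],
                   col = grDevices::adjustcolor(col, alpha.f = 0.45),
                   border = NA)
    graphics::text(i, su[i] + 0.08, tot$surgeries[i], cex = 0.8)
    graphics::text(i, -fu[i] - 0.08, tot$frames[i], cex = 0.8)
  }
  graphics::axis(1, at = seq_len(nrow(tot)), labels = tot$set)
  graphics::abline(h = 0)
  graphics::mtext("surgeries (up) / frames (down)", side = 2, line = 1, cex = 0.8)
  # per-surgery durations with dashed means
  per <- model$per_surgery
  graphics::par(mar = c(6, 4, 3, 1))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0.5, nrow(per) + 0.5),
                        ylim = c(0, 1.08 * max(per$frames)))
  graphics::title(main = "Surgery durations")
  graphics::rect(per$x - 0.4, 0, per$x + 0.4, per$frames,
                 col = style$set_colors[per$set], border = NA)
  for (s in model$sets_present) {
    xs <- per$x[per$set == s]
    m <- model$means$mean_frames[model$means$set == s]
    if (length(xs) && !is.na(m)) {
      graphics::segments(min(xs) - 0.4, m, max(xs) + 0.4, m, lty = 2,
                         col = "grey20")
    }
  }
  graphics::axis(2)
  graphics::axis(1, at = per$x, labels = per$surgery_id, las = 2, cex.axis = 0.6)
  graphics::mtext("frames", side = 2, line = 2.5, cex = 0.8)
  invisible(file)
}

#' Write an audit report to disk
#'
#' JSON output is a versioned schema that round-trips losslessly through
#' [read_report()]; Markdown contains the kind-by-set summary matrix plus the
#' flagged-attribute list; CSV is the per-attribute wide table.
#'
#' @param report an [audit_splits()] result.
#' @param path output path.
#' @param format `"json"`, `"markdown"` or `"csv"`; default guessed from the
#'   file extension.
#' @export
write_report <- function(report, path, format = NULL) {
  stopifnot(inherits(report, "audit_report"))
  format <- format %||% switch(tolower(tools::file_ext(path)),
                               json = "json", md = "markdown",
                               markdown = "markdown", csv = "csv",
                               stop("cannot guess report format from: ", path))
  if (format == "json") {
    obj <- list(schema = "splitaudit/audit-report/v1",
                name = report$name, semantics = report$semantics,
                sets_present = as.list(report$sets_present),
                counts = report$counts,
                unrepresented = report$unrepresented,
                summary = data.frame(kind = rownames(report$summary),
                                     report$summary, check.names = FALSE),
                totals = report$totals)
    jsonlite::write_json(obj, path, dataframe = "columns", auto_unbox = TRUE,
                         digits = NA, na = "null", null = "null")
  } else if (format == "markdown") {
    lines <- c(sprintf("# Split audit: %s", report$name), "",
               sprintf("Combination semantics: %s. Non-empty sets: %s.",
                       report$semantics,
                       paste(report$sets_present, collapse = ", ")), "",
               "## Unrepresented attributes (kind x absent-in set)", "",
               paste0("| kind | ", paste(paste0("absent_in_", .SETS),
                                         collapse = " | "), " |"),
               paste0("|", paste(rep("---", 4L), collapse = "|"), "|"))
    for (k in rownames(report$summary)) {
      vals <- ifelse(is.na(report$summary[k, ]), "N/A", report$summary[k, ])
      lines <- c(lines, paste0("| ", k, " | ", paste(vals, collapse = " | "), " |"))
    }
    lines <- c(lines, "", "## Per-set totals", "",
               "| set | surgeries | frames | mean frames |",
               "|---|---|---|---|")
    for (i in seq_len(nrow(report$totals))) {
      t <- report$totals[i, ]
      lines <- c(lines, sprintf("| %s | %d | %d | %s |", t$set, t$surgeries,
                                t$frames,
                                if (is.na(t$mean_frames)) "-" else
                                  sprintf("%.1f", t$mean_frames)))
    }
    if (nrow(report$unrepresented)) {
      lines <- c(lines, "", "## Flagged attributes", "")
      f <- report$unrepresented
      lines <- c(lines, sprintf("- **%s** `%s` absent in: %s", f$kind, f$key,
                                f$absent_in))
    }
    writeLines(lines, path)
  } else {
    f <- report$unrepresented
    utils::write.csv(f, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a JSON audit report back
#'
#' @param path path written by [write_report()] with JSON format.
#' @return object of class `audit_report` (components `counts`,
#'   `unrepresented`, `summary`, `totals` reconstructed).
#' @export
read_report <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "splitaudit/audit-report/v1")) {
    stop("not a splitaudit audit-report JSON: ", path)
  }
  summary_df <- as.data.frame(obj$summary, stringsAsFactors = FALSE)
  summary <- as.matrix(summary_df[, .SETS, drop = FALSE])
  rownames(summary) <- summary_df$kind
  storage.mode(summary) <- "integer"
  names(dimnames(summary)) <- c("kind", "absent_in")
  counts <- as.data.frame(obj$counts, stringsAsFactors = FALSE)
  unrep <- as.data.frame(obj$unrepresented, stringsAsFactors = FALSE)
  if (!nrow(unrep)) {
    unrep <- data.frame(kind = character(), key = character(),
                        train = integer(), val = integer(), test = integer(),
                        absent_in = character(), stringsAsFactors = FALSE)
  }
  structure(list(name = obj$name, semantics = obj$semantics,
                 sets_present = unlist(obj$sets_present),
                 counts = counts, unrepresented = unrep, summary = summary,
                 totals = as.data.frame(obj$totals, stringsAsFactors = FALSE)),
            class = "audit_report")
}
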