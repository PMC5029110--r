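#' n-way Venn intersects
#'
#' Assigns every element of the union of the input sets to exactly one
#' disjoint occupancy region: the region keyed by the full subset of sets
#' that contain it. Works for 2 to 20 sets (2^20 - 1 candidate regions);
#' 2-5-way results can be drawn with \code{\link{venn_counts_plot}}.
#' Duplicate identifiers within a set are collapsed.
#'
#' @param sets named list (length >= 2) of identifier vectors.
#' @return An object of class \code{venn_result}: \code{set_names},
#'   \code{regions} (named list of members per occupied region, keys are
#'   sorted set names joined by \code{"&"}), \code{counts} (occupied-region
#'   sizes). Use \code{\link{venn_counts}} to include empty regions.
#' @examples
#' v <- overlapper(list(A = 1:3, B = 2:4, C = c(3, 5)))
#' venn_counts(v)
#' @export
overlapper <- function(sets) {
  if (length(sets) < 2L) stop("need at least 2 sets", call. = FALSE)
  if (length(sets) > 20L)
    stop("more than 20 sets: full region computation is infeasible, ",
         "compute pairwise overlaps instead", call. = FALSE)
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("sets must be named", call. = FALSE)
  if (anyDuplicated(names(sets)))
    stop("set names must be unique", call. = FALSE)
  sets <- lapply(sets, function(s) unique(as.character(s)))
  union_ <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) union_ %in% s,
                   logical(length(union_)))
  if (length(union_) == 1L) member <- matrix(member, nrow = 1L)
  keys <- apply(member, 1L, function(m)
    paste(sort(names(sets)[m]), collapse = "&"))
  regions <- split(union_, keys)
  structure(list(set_names = names(sets), regions = regions,
                 counts = lengths(regions)),
            class = "venn_result")
}

#' @export
print.venn_result <- function(x, ...) {
  cat(sprintf("Venn intersects of %d sets (%s): %d occupied region(s)\n",
              length(x$set_names), paste(x$set_names, collapse = ", "),
              length(x$regions)))
  print(x$counts)
  invisible(x)
}

#' Region counts of a Venn result
#' @param x a \code{\link{overlapper}} result.
#' @param complete include empty regions (count 0); requires at most 20 sets.
#' @return Named integer vector of region counts.
#' @export
venn_counts <- function(x, complete = TRUE) {
  stopifnot(inherits(x, "venn_result"))
  if (!complete) return(x$counts)
  nm <- x$set_names
  keys <- unlist(lapply(seq_along(nm), function(k)
    apply(utils::combn(sort(nm), k), 2L, paste, collapse = "&")))
  out <- stats::setNames(integer(length(keys)), keys)
  out[names(x$counts)] <- x$counts
  out
}

# ---- Venn diagram ----------------------------------------------------------

# Shape parameters per set count: circles (n<=3) or rotated ellipses
# (n = 4, 5). Region label positions are computed numerically as the
# centroid of the grid points whose ellipse-membership pattern matches the
# region, so every one of the 2^n - 1 regions gets its label inside its own
# area.
.venn_shapes <- function(n) {
  deg <- pi / 180
  switch(as.character(n),
    "2" = data.frame(cx = c(-0.35, 0.35), cy = 0, a = 0.72, b = 0.72, ang = 0),
    "3" = data.frame(cx = c(0, -0.4, 0.4), cy = c(0.4, -0.3, -0.3),
                     a = 0.72, b = 0.72, ang = 0),
    "4" = data.frame(cx = c(-0.30, -0.10, 0.10, 0.30),
                     cy = c(-0.12, 0.06, 0.06, -0.12),
                     a = 0.75, b = 0.42,
                     ang = c(-50, -50, 50, 50) * deg),
    "5" = {
      th <- (90 + 72 * (0:4)) * deg
      data.frame(cx = 0.16 * cos(th), cy = 0.16 * sin(th),
                 a = 0.6, b = 0.38, ang = th + 22 * deg)
    },
    stop("Venn diagrams support 2 to 5 sets", call. = FALSE))
}

.in_ellipse <- function(x, y, sh) {
  dx <- x - sh$cx; dy <- y - sh$cy
  u <- dx * cos(sh$ang) + dy * sin(sh$ang)
  v <- -dx * sin(sh$ang) + dy * cos(sh$ang)
  (u / sh$a)^2 + (v / sh$b)^2 <= 1
}

.venn_label_pos <- function(shapes, grid_n = 251L) {
  g <- seq(-1.35, 1.35, length.out = grid_n)
  pts <- expand.grid(x = g, y = g)
  memb <- vapply(seq_len(nrow(shapes)), function(i)
    .in_ellipse(pts$x, pts$y, shapes[i, ]), logical(nrow(pts)))
  key <- apply(memb, 1L, function(m)
    if (any(m)) paste(which(m), collapse = ",") else "")
  keep <- key != ""
  xs <- tapply(pts$x[keep], key[keep], mean)
  ys <- tapply(pts$y[keep], key[keep], mean)
  list(x = xs, y = ys)
}

#' Draw a 2-5-way Venn diagram with region counts
#'
#' One numeric label per disjoint region, equal to the
#' \code{\link{venn_counts}} value (zeros included). More than five sets
#' cannot be drawn; use the count table instead.
#'
#' @param result an \code{\link{overlapper}} result with 2-5 sets.
#' @param out figure path (\code{.pdf} or \code{.png}).
#' @return \code{out}, invisibly.
#' @export
venn_counts_plot <- function(result, out) {
  stopifnot(inherits(result, "venn_result"))
  n <- length(result$set_names)
  if (n > 5L)
    stop("cannot draw a Venn diagram for ", n,
         " sets; use venn_counts() for the count table", call. = FALSE)
  shapes <- .venn_shapes(n)
  pos <- .venn_label_pos(shapes)
  counts <- venn_counts(result, complete = TRUE)
  nm_sorted <- result$set_names
  if (grepl("\\.png$", out)) grDevices::png(out, 700, 700, res = 100)
  else grDevices::pdf(out, 7, 7)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(1, 1, 2, 1))
  graphics::plot(NA, xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4), axes = FALSE,
                 xlab = "", ylab = "", asp = 1,
                 main = paste(nm_sorted, collapse = " / "))
  th <- seq(0, 2 * pi, length.out = 200)
  cols <- grDevices::hcl.colors(n, "Dark 3", alpha = 0.25)
  for (i in seq_len(n)) {
    sh <- shapes[i, ]
    xs <- sh$cx + sh$a * cos(th) * cos(sh$ang) - sh$b * sin(th) * sin(sh$ang)
    ys <- sh$cy + sh$a * cos(th) * sin(sh$ang) + sh$b * sin(th) * cos(sh$ang)
    graphics::polygon(xs, ys, col = cols[i], border = "grey30")
    # set label outside its shape, away from the centre
    lx <- sh$cx * 2.1 + 0.12 * cos(sh$ang); ly <- sh$cy * 2.1 + 0.3
    graphics::text(lx, ly, nm_sorted[i], font = 2, cex = 0.9)
  }
  for (key in names(pos$x)) {
    idx <- as.integer(strsplit(key, ",")[[1]])
    rkey <- paste(sort(nm_sorted[idx]), collapse = "&")
    graphics::text(pos$x[[key]], pos$y[[key]], counts[[rkey]], cex = 0.9)
  }
  invisible(out)
}

# ---- DEG filtering ---------------------------------------------------------

#' Filter a differential-expression result table
#'
#' Consumes a per-gene table carrying, for each sample comparison, a paired
#' log2 fold-change column \code{<comparison>_logFC} and an adjusted p-value
#' column \code{<comparison>_FDR} (as produced by upstream DE tools run on
#' the comparison sets of the targets file). A gene is called up-regulated
#' in a comparison when \code{logFC >= lfc_min} and \code{FDR <= fdr_max},
#' down-regulated when \code{logFC <= -lfc_min} and \code{FDR <= fdr_max};
#' missing values never pass. The sign convention follows the comparison
#' pair ordering of the targets file: positive fold change means higher in
#' the first-named factor of \code{"A-B"}.
#'
#' @param deg_table data.frame; gene identifiers are taken from a
#'   \code{gene} column if present, else from row names.
#' @param lfc_min non-negative log2 fold-change cutoff.
#' @param fdr_max FDR cutoff in (0, 1].
#' @return An object of class \code{deg_filter_result}: \code{up} and
#'   \code{down} (named lists of gene vectors per comparison),
#'   \code{summary} (data.frame comparison, n_up, n_down, n_total) and
#'   \code{cutoffs}.
#' @export
filter_degs <- function(deg_table, lfc_min = 1, fdr_max = 0.05) {
  stopifnot(lfc_min >= 0, fdr_max > 0, fdr_max <= 1)
  deg_table <- as.data.frame(deg_table)
  genes <- if ("gene" %in% names(deg_table)) as.character(deg_table$gene)
           else rownames(deg_table)
  lfc_cols <- grep("_logFC$", names(deg_table), value = TRUE)
  fdr_cols <- grep("_FDR$", names(deg_table), value = TRUE)
  cmp_l <- sub("_logFC$", "", lfc_cols)
  cmp_f <- sub("_FDR$", "", fdr_cols)
  orphan <- c(setdiff(cmp_l, cmp_f), setdiff(cmp_f, cmp_l))
  if (length(orphan))
    stop("comparison ", orphan[[1]],
         " lacks a matching logFC/FDR column pair", call. = FALSE)
  if (!length(cmp_l)) stop("no <comparison>_logFC/_FDR column pairs found",
                           call. = FALSE)
  up <- list(); down <- list(); rows <- list()
  for (cmp in cmp_l) {
    lfc <- deg_table[[paste0(cmp, "_logFC")]]
    fdr <- deg_table[[paste0(cmp, "_FDR")]]
    pass <- !is.na(lfc) & !is.na(fdr) & fdr <= fdr_max
    up[[cmp]] <- genes[pass & lfc >= lfc_min]
    down[[cmp]] <- genes[pass & lfc <= -lfc_min]
    rows[[cmp]] <- data.frame(comparison = cmp,
                              n_up = length(up[[cmp]]),
                              n_down = length(down[[cmp]]),
                              n_total = length(up[[cmp]]) + length(down[[cmp]]),
                              stringsAsFactors = FALSE)
  }
  structure(list(up = up, down = down,
                 summary = do.call(rbind, c(rows, make.row.names = FALSE)),
                 cutoffs = c(lfc_min = lfc_min, fdr_max = fdr_max)),
            class = "deg_filter_result")
}

#' @export
print.deg_filter_result <- function(x, ...) {
  cat(sprintf("DEG filtering at |logFC| >= %g, FDR <= %g\n",
              x$cutoffs[["lfc_min"]], x$cutoffs[["fdr_max"]]))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
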