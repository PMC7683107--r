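#' Midline parameters
#'
#' The brain midline is parameterized as the line through the point
#' `(cx + offset, cy)` (image centre plus a horizontal displacement, in
#' pixels) tilted by `angle` degrees from vertical, i.e. the set of points
#' `x = cx + offset + tan(angle) * (y - cy)` in 0-based (x, y) pixel
#' coordinates.
#'
#' @param offset signed horizontal displacement at the centre row, pixels.
#' @param angle tilt from vertical, degrees; |angle| <= 30.
#' @export
midline_params <- function(offset = 0, angle = 0) {
  if (abs(angle) > 30) stop("midline angle must be within 30 degrees of vertical")
  structure(list(offset = offset, angle = angle), class = "midline_params")
}

#' @export
print.midline_params <- function(x, ...) {
  cat(sprintf("<midline> offset %.2f px, angle %.2f deg\n", x$offset, x$angle))
  invisible(x)
}

# Reflect 0-based (x, y) coordinates across a midline.
reflect_xy <- function(x, y, midline, dim2) {
  cx <- (dim2[2] - 1) / 2; cy <- (dim2[1] - 1) / 2
  a <- midline$angle * pi / 180
  dx <- sin(a); dy <- cos(a)                 # unit direction of the line
  px <- cx + midline$offset; py <- cy
  vx <- x - px; vy <- y - py
  dot <- vx * dx + vy * dy
  list(x = 2 * (px + dot * dx) - x, y = 2 * (py + dot * dy) - y)
}

#' Estimate the brain midline by reflection correlation
#'
#' Searches a grid of (offset, angle) candidates for the line maximizing the
#' Pearson correlation between the brain-masked image and its reflection
#' across the candidate line.  A coarse pass (2 px / 1 deg) is refined
#' locally at the full grid resolution; ties prefer the smallest |angle|,
#' then the smallest |offset|.
#'
#' @param slice an [image_slice()] or matrix.
#' @param brain_mask logical mask with at least 100 foreground pixels.
#' @param offset_grid,angle_grid candidate offsets (px) and angles (deg).
#' @param max_points subsample cap on mask pixels used for scoring.
#' @return A [midline_params()] with attribute `score`.
#' @export
estimate_midline <- function(slice, brain_mask,
                             offset_grid = seq(-20, 20, by = 1),
                             angle_grid = seq(-10, 10, by = 0.5),
                             max_points = 6000) {
  slice <- as_slice(slice)
  v <- slice$values
  brain_mask <- roi_mask(brain_mask)
  if (sum(brain_mask) < 100) stop("degenerate brain mask (< 100 px)")
  idx <- which(brain_mask)
  if (length(idx) > max_points)
    idx <- idx[seq(1, length(idx), length.out = max_points)]
  nr <- nrow(v)
  x0 <- (idx - 1) %/% nr    # 0-based col
  y0 <- (idx - 1) %% nr     # 0-based row
  vals <- v[idx]
  score_one <- function(off, ang) {
    rf <- reflect_xy(x0, y0, list(offset = off, angle = ang), dim(v))
    ri <- round(rf$y) + 1; ci <- round(rf$x) + 1
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= ncol(v)
    ok[ok] <- brain_mask[cbind(ri[ok], ci[ok])]
    if (sum(ok) < 50) return(-Inf)
    suppressWarnings(cc <- cor(vals[ok], v[cbind(ri[ok], ci[ok])]))
    if (is.na(cc)) 0 else cc
  }
  best_over <- function(offs, angs) {
    grid <- expand.grid(offset = offs, angle = angs)
    grid <- grid[order(abs(grid$angle), abs(grid$offset)), ]
    sc <- mapply(score_one, grid$offset, grid$angle)
    i <- which.max(sc)   # first max under the tie-break ordering
    list(offset = grid$offset[i], angle = grid$angle[i], score = sc[i])
  }
  co <- offset_grid[seq(1, length(offset_grid), by = 4)]
  ca <- angle_grid[seq(1, length(angle_grid), by = 4)]
  coarse <- best_over(unique(c(co, 0)), unique(c(ca, 0)))
  fine <- best_over(offset_grid[abs(offset_grid - coarse$offset) <= 4.1],
                    angle_grid[abs(angle_grid - coarse$angle) <= 2.1])
  out <- midline_params(fine$offset, fine$angle)
  attr(out, "score") <- fine$score
  out
}

#' Mirror an ROI across a midline
#'
#' Reflects a binary mask across the line by nearest-neighbour inverse
#' mapping (reflection is its own inverse, so the output has no holes).
#' Errors if the reflected mask is empty; warns when part of it is cropped
#' at the image border.
#'
#' @param mask logical matrix, nonempty.
#' @param midline a [midline_params()].
#' @return logical matrix, same shape.
#' @export
mirror_roi <- function(mask, midline) {
  mask <- roi_mask(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  x0 <- (idx - 1) %/% nr; y0 <- (idx - 1) %% nr
  fw <- reflect_xy(x0, y0, midline, dim(mask))
  n_in <- sum(fw$x > -0.5 & fw$x < nc - 0.5 & fw$y > -0.5 & fw$y < nr - 0.5)
  if (n_in == 0) stop("mirrored ROI leaves the image entirely")
  if (n_in < length(idx))
    warning("mirrored ROI partially cropped at the image border")
  # inverse mapping over the full grid: reflect every output pixel and read
  xs <- rep(0:(nc - 1), each = nr); ys <- rep(0:(nr - 1), times = nc)
  rf <- reflect_xy(xs, ys, midline, dim(mask))
  ri <- round(rf$y) + 1; ci <- round(rf$x) + 1
  ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
  out <- rep(FALSE, nr * nc)
  out[ok] <- mask[cbind(ri[ok], ci[ok])]
  matrix(out, nr, nc)
}

#' Build candidate lesion/mirror region pairs for a subject
#'
#' For every slice of the subject, estimates (or is given) the midline,
#' mirrors the ROI across it, clips the mirror to the brain, and returns the
#' (region, mirrored region) pair.  Mirrors retaining less than half their
#' area after clipping drop the pair with a message.  Labels follow the
#' subject group: `lesion`/`mirror` or `normal`/`normal_mirror`.
#'
#' @param subject a `synthetic_subject` from [generate_cohort()].
#' @param midline optional [midline_params()] reused for all slices;
#'   `NULL` estimates one per slice from the image.
#' @return list of pairs; each pair is a list of two candidate regions
#'   (`slice`, `mask`, `label`, `subject_id`, `pairing_id`).
#' @export
make_candidate_pairs <- function(subject, midline = NULL) {
  out <- list()
  for (k in seq_along(subject$slices)) {
    rec <- subject$slices[[k]]
    ml <- midline %||%
      tryCatch(estimate_midline(rec$slice, rec$brain),
               error = function(e) stop("subject ", subject$subject_id, ": ",
                                        conditionMessage(e)))
    mir <- tryCatch(suppressWarnings(mirror_roi(rec$mask, ml)),
                    error = function(e) stop("subject ", subject$subject_id,
                                             ": ", conditionMessage(e)))
    clipped <- mir & rec$brain
    if (sum(clipped) < 0.5 * sum(mir)) {
      msg("dropping pair ", subject$subject_id, " slice ", k,
          ": mirror mostly outside brain")
      next
    }
    labs <- if (subject$group == "lesion") c("lesion", "mirror")
            else c("normal", "normal_mirror")
    pid <- sprintf("%s_s%d", subject$subject_id, k)
    mk <- function(mask, label) list(slice = rec$slice, mask = mask,
                                     label = label,
                                     subject_id = subject$subject_id,
                                     pairing_id = pid, midline = ml)
    out[[length(out) + 1]] <- list(mk(rec$mask, labs[1]),
                                   mk(clipped, labs[2]))
  }
  out
}
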