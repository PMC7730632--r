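#' Foreground segmentation of a depth frame
#'
#' Pixels with a valid reading nearer than `max_subject_depth_mm` are
#' foreground; of the resulting connected components only the largest is
#' kept (ties broken toward the leftmost component), so a seated subject
#' is isolated from background clutter without any trained detector.
#'
#' @param frame integer matrix of depth values in mm (0 = invalid).
#' @param max_subject_depth_mm scalar threshold; the subject must be
#'   nearer than this, the background farther.
#' @return Logical matrix, `TRUE` on the subject silhouette.
#' @export
segment_foreground <- function(frame, max_subject_depth_mm) {
  stopifnot_scalar_number(max_subject_depth_mm, "max_subject_depth_mm",
                          min = 0, strict_min = TRUE)
  if (!is.matrix(frame))
    abort_respdepth("validation", "`frame` must be a matrix")
  mask <- frame > 0 & frame < max_subject_depth_mm
  if (!any(mask))
    abort_respdepth("detection", "empty foreground: no pixel below threshold")
  lab <- EBImage::bwlabel(mask * 1L)
  lab <- EBImage::imageData(lab)
  sizes <- tabulate(lab[lab > 0])
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # tie: leftmost component (smallest column index of any member pixel)
    mincol <- vapply(best, function(l) min(col(lab)[lab == l]), numeric(1))
    best <- best[which.min(mincol)]
  }
  lab == best
}

# 3x3 morphological closing; heals single-pixel dropout holes in a mask
close_mask <- function(mask) {
  k <- EBImage::makeBrush(3, shape = "box")
  out <- EBImage::closing(mask * 1, k)
  EBImage::imageData(out) > 0.5
}

mask_bbox <- function(mask) {
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  # 0-based, half-open
  list(top = rows[1] - 1L, bottom = rows[length(rows)],
       left = cols[1] - 1L, right = cols[length(cols)])
}

#' Upper-body detection
#'
#' Locates the head-and-shoulders area on the initial frame.  The
#' default backend thresholds the depth frame ([segment_foreground()])
#' and returns the bounding box of the silhouette rows above its
#' vertical midpoint, widened to the full silhouette width.  A
#' pretrained external detector can be plugged in by passing a function
#' `frame -> list(top, bottom, left, right)` (0-based, half-open).
#'
#' @param frame depth (or intensity) frame matrix.
#' @param detector `"foreground"` (default) or a detector function.
#' @param max_subject_depth_mm threshold for the foreground backend.
#' @return A body box: list `top, bottom, left, right`, 0-based
#'   half-open pixel bounds.
#' @export
detect_upper_body <- function(frame, detector = "foreground",
                              max_subject_depth_mm = 2000) {
  if (is.function(detector)) {
    box <- detector(frame)
    if (is.null(box))
      abort_respdepth("detection",
        "external detector found nothing; try detector = \"foreground\"")
    return(validate_box(box, nrow(frame), ncol(frame)))
  }
  if (!identical(detector, "foreground"))
    abort_respdepth("validation", "unknown detector backend")
  mask <- segment_foreground(frame, max_subject_depth_mm)
  bb <- mask_bbox(mask)
  mid <- bb$top + floor((bb$bottom - bb$top) / 2)
  validate_box(list(top = bb$top, bottom = mid,
                    left = bb$left, right = bb$right),
               nrow(frame), ncol(frame))
}

validate_box <- function(box, height, width) {
  b <- lapply(box[c("top", "bottom", "left", "right")], as.integer)
  if (!(b$top < b$bottom && b$bottom <= height &&
        b$left < b$right && b$right <= width) || b$top < 0 || b$left < 0)
    abort_respdepth("validation", "invalid body box bounds")
  b
}

# Ramer-Douglas-Peucker polyline simplification on an open chain of
# points (n x 2 matrix); returns indices of retained vertices.
rdp_indices <- function(pts, eps) {
  n <- nrow(pts)
  if (n <= 2L) return(seq_len(n))
  keep <- logical(n)
  keep[c(1L, n)] <- TRUE
  stack <- list(c(1L, n))
  while (length(stack) > 0) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- seg[1]; j <- seg[2]
    if (j - i < 2L) next
    a <- pts[i, ]; b <- pts[j, ]
    ab <- b - a
    len <- sqrt(sum(ab^2))
    idx <- (i + 1L):(j - 1L)
    if (len < .Machine$double.eps) {
      d <- sqrt((pts[idx, 1] - a[1])^2 + (pts[idx, 2] - a[2])^2)
    } else {
      d <- abs(ab[2] * (pts[idx, 1] - a[1]) - ab[1] * (pts[idx, 2] - a[2])) / len
    }
    dmax <- max(d)
    if (dmax > eps) {
      k <- idx[which.max(d)]
      keep[k] <- TRUE
      stack[[length(stack) + 1L]] <- c(i, k)
      stack[[length(stack) + 1L]] <- c(k, j)
    }
  }
  which(keep)
}

# Simplify a closed contour (n x 2, ordered): split at the two mutually
# farthest of {first point, farthest point from it}, run RDP on both
# halves, and rejoin.
simplify_closed_contour <- function(pts, eps) {
  n <- nrow(pts)
  if (n <= 3L) return(pts)
  d1 <- (pts[, 1] - pts[1, 1])^2 + (pts[, 2] - pts[1, 2])^2
  k <- which.max(d1)
  half1 <- pts[1:k, , drop = FALSE]
  half2 <- pts[c(k:n, 1L), , drop = FALSE]
  i1 <- rdp_indices(half1, eps)
  i2 <- rdp_indices(half2, eps)
  v <- rbind(half1[i1, , drop = FALSE],
             half2[i2[-c(1L, length(i2))], , drop = FALSE])
  unique(v)
}

# Turn angle (radians, in [0, pi]) and convexity of each vertex of a
# closed polygon (m x 2).  Convex = turning toward the polygon interior.
polygon_turns <- function(v) {
  m <- nrow(v)
  prev <- v[c(m, 1:(m - 1)), , drop = FALSE]
  nxt <- v[c(2:m, 1L), , drop = FALSE]
  e1 <- v - prev
  e2 <- nxt - v
  cross <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  dot <- e1[, 1] * e2[, 1] + e1[, 2] * e2[, 2]
  turn <- atan2(abs(cross), dot)
  # polygon orientation from the signed area
  area2 <- sum(v[, 1] * nxt[, 2] - nxt[, 1] * v[, 2])
  convex <- if (area2 >= 0) cross >= 0 else cross <= 0
  list(turn = turn, convex = convex)
}

#' Shoulder detection on a silhouette mask
#'
#' The silhouette contour is polygon-approximated (Ramer-Douglas-Peucker
#' with tolerance 2 % of the silhouette height) and each shoulder is the
#' most convex vertex -- the largest turn angle -- within the lateral
#' third of the upper-body box on its side, where the contour turns from
#' the near-vertical neck/arm line to the near-horizontal shoulder run.
#' Ties go to the vertex closer to the head (top-centre of the box).
#' Assumes a seated subject with lowered arms.  A 3x3 morphological
#' closing is applied first to heal sensor dropout holes.
#'
#' @param mask logical silhouette matrix (from [segment_foreground()]).
#' @param box upper-body box from [detect_upper_body()].
#' @param eps_px polygon tolerance in pixels; default 2 % of the
#'   silhouette's row extent.
#' @return A shoulder pair: list with `left` and `right`, each `c(row,
#'   col)` in 0-based image coordinates, `left` having the smaller
#'   column.
#' @export
detect_shoulders <- function(mask, box, eps_px = NULL) {
  if (!any(mask))
    abort_respdepth("detection", "empty mask")
  box <- validate_box(box, nrow(mask), ncol(mask))
  mask <- close_mask(mask)
  bb <- mask_bbox(mask)
  if (is.null(eps_px)) eps_px <- 0.02 * (bb$bottom - bb$top)
  oc <- EBImage::ocontour(mask * 1L)
  pts <- oc[[which.max(vapply(oc, nrow, numeric(1)))]]  # largest object
  verts <- simplify_closed_contour(pts, eps_px)
  if (nrow(verts) < 3L)
    abort_respdepth("detection", "contour degenerated during approximation")
  tt <- polygon_turns(verts)

  w <- box$right - box$left
  third <- w / 3
  head_pt <- c(box$top, box$left + w / 2)
  in_rows <- verts[, 1] >= box$top & verts[, 1] < box$bottom
  cand_left <- which(tt$convex & in_rows & verts[, 2] < box$left + third)
  cand_right <- which(tt$convex & in_rows & verts[, 2] >= box$right - third)
  if (length(cand_left) == 0L || length(cand_right) == 0L)
    abort_respdepth("detection",
                    "fewer than 2 candidate shoulder vertices in the box")

  pick <- function(cand) {
    turns <- tt$turn[cand]
    best <- cand[turns == max(turns)]
    if (length(best) > 1L) {
      d <- (verts[best, 1] - head_pt[1])^2 + (verts[best, 2] - head_pt[2])^2
      best <- best[which.min(d)]
    }
    as.integer(verts[best, ])
  }
  l <- pick(cand_left)
  r <- pick(cand_right)
  if (l[2] >= r[2])
    abort_respdepth("detection", "shoulder candidates do not straddle the body")
  list(left = l, right = r)
}
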