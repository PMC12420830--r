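#' Match detected centroids to ground truth and score detection
#'
#' One-to-one matching of detected to true centroids within a distance
#' gate: candidate pairs inside the gate are sorted by distance and matched
#' greedily, each point used at most once. For well-separated objects
#' (spacing beyond the gate) this coincides with the optimal assignment.
#' Precision is matched detections over all detections; recall is matched
#' truths over all truths.
#'
#' @param detected,truth data.frames with `x`, `y` (pixels).
#' @param gate_um matching gate in micrometres.
#' @param pixel_size micrometres per pixel (1 = gate in pixels).
#' @return list with `matches` (data.frame detected/truth row indices and
#'   distance in um), `precision`, `recall`, `f1`, `mean_distance_um`.
#' @export
match_centroids <- function(detected, truth, gate_um = 5, pixel_size = 1) {
  nd <- nrow(detected); nt <- nrow(truth)
  if (nd == 0 || nt == 0) {
    return(list(matches = data.frame(detected = integer(0),
                                     truth = integer(0),
                                     distance_um = numeric(0)),
                precision = if (nd == 0) NA_real_ else 0,
                recall = if (nt == 0) NA_real_ else 0,
                f1 = 0, mean_distance_um = NA_real_))
  }
  d <- sqrt(outer(detected$x, truth$x, "-")^2 +
              outer(detected$y, truth$y, "-")^2) * pixel_size
  cand <- which(d <= gate_um, arr.ind = TRUE)
  ord <- order(d[cand])
  used_d <- logical(nd); used_t <- logical(nt)
  mi <- integer(0); mj <- integer(0)
  for (r in ord) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (used_d[i] || used_t[j]) next
    used_d[i] <- TRUE; used_t[j] <- TRUE
    mi <- c(mi, i); mj <- c(mj, j)
  }
  m <- data.frame(detected = mi, truth = mj,
                  distance_um = d[cbind(mi, mj)])
  precision <- nrow(m) / nd
  recall <- nrow(m) / nt
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(matches = m, precision = precision, recall = recall, f1 = f1,
       mean_distance_um = if (nrow(m)) mean(m$distance_um) else NA_real_)
}
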