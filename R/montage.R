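## Synthetic 128-channel montage in the style of a BioSemi ABCD layout.
## Positions are a deterministic golden-angle spiral on the upper unit
## hemisphere (+y = front). They are *not* real electrode coordinates; they
## only need to support nearest-neighbour interpolation, frontal-channel
## designation and region-based resting pools.

#' Build the synthetic electrode montage
#'
#' The full layout has 128 channels labelled `A1..A32, B1..B32, C1..C32,
#' D1..D32`. Smaller montages (`n_channels >= 16`) are label subsets of the
#' full layout that always retain the channels of the ERP Central and
#' Parietal pools, so reduced-channel simulations remain analyzable.
#'
#' @param n_channels 16..128.
#' @return data.frame with `label`, `x`, `y`, `z`, `frontal` (logical; the
#'   designated blink carriers are the three most frontal channels).
#' @export
build_montage <- function(n_channels = 128) {
  n_channels <- as.integer(n_channels)
  if (n_channels < 16L || n_channels > 128L) {
    stop("n_channels must be between 16 and 128", call. = FALSE)
  }
  labels128 <- paste0(rep(c("A", "B", "C", "D"), each = 32L), rep(1:32, 4L))
  i <- seq_len(128L)
  z <- 0.05 + 0.9 * (i - 1) / 127
  golden <- pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  full <- data.frame(
    label = labels128,
    x = r * cos(golden * i),
    y = r * sin(golden * i),
    z = z,
    stringsAsFactors = FALSE
  )
  if (n_channels == 128L) {
    m <- full
  } else {
    keep <- unique(c(erp_pool_labels()$central, erp_pool_labels()$parietal))
    rest <- setdiff(labels128, keep)
    m <- full[match(c(keep, rest[seq_len(n_channels - length(keep))]),
                    full$label), ]
    rownames(m) <- NULL
  }
  m$frontal <- rank(-m$y, ties.method = "first") <= 3L
  m
}

#' ERP electrode-pool label sets
#'
#' Default memberships of the Central (N400) and Parietal (LPC) pools. Note:
#' the source figure lists D16 both as a central-pool member and, in the
#' parietal pool, with a prefrontal site name; the listed labels are used
#' as-is and the conflict is documented rather than resolved.
#'
#' @return list with character vectors `central` and `parietal`.
#' @export
erp_pool_labels <- function() {
  list(
    central  = c("A1", "A2", "A3", "D1", "D14", "D15", "D16"),
    parietal = c("A3", "A4", "A5", "A6", "A20", "A21", "D16", "D17")
  )
}

#' Resting-state electrode pools from montage geometry
#'
#' Channels are partitioned into five scalp regions -- medial-frontal,
#' left/right frontotemporal and left/right posterior -- by nearest-centroid
#' assignment on the montage coordinates, approximating the schematic pool
#' layout of the emulated analysis.
#'
#' @param montage data.frame from [build_montage()].
#' @return named list of character vectors of channel labels.
#' @export
resting_pools <- function(montage) {
  centroids <- rbind(
    medial_frontal     = c(0, 0.75, 0.65),
    left_frontotemp    = c(-0.85, 0.35, 0.4),
    right_frontotemp   = c(0.85, 0.35, 0.4),
    left_posterior     = c(-0.6, -0.7, 0.4),
    right_posterior    = c(0.6, -0.7, 0.4)
  )
  xyz <- as.matrix(montage[, c("x", "y", "z")])
  d <- vapply(seq_len(nrow(centroids)), function(k) {
    rowSums(sweep(xyz, 2L, centroids[k, ])^2)
  }, numeric(nrow(xyz)))
  assign <- max.col(-d)
  pools <- split(montage$label, rownames(centroids)[assign])
  pools <- pools[rownames(centroids)] # fixed order
  if (any(vapply(pools, length, 1L) == 0L)) {
    stop("montage too sparse: an empty resting pool", call. = FALSE)
  }
  pools
}

#' Write / read a montage as TSV
#' @param montage data.frame from [build_montage()].
#' @param path file path.
#' @export
write_montage <- function(montage, path) {
  utils::write.table(montage, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "x", "y", "z", "frontal") %in% names(m)))
  m$frontal <- as.logical(m$frontal)
  m
}
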