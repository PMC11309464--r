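#' Default 10-20 scalp montage
#'
#' Channel labels and schematic 2-D positions for a 20-channel 10-20 montage,
#' ordered anterior-to-posterior and left-to-right. The ordering defines the
#' default channel adjacency (consecutive rows) used by the cluster analysis,
#' and the positions drive topographies in the simulator and neighbour-based
#' channel interpolation.
#'
#' @param n_channels number of channels (2..20). For fewer than 20 channels an
#'   evenly spaced subset of the full montage is used (midline channels are
#'   retained where possible), which keeps reduced-size simulations meaningful.
#' @return data.frame with columns `label`, `x`, `y`.
#' @export
#' @examples
#' head(default_montage())
default_montage <- function(n_channels = 20) {
  full <- data.frame(
    label = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
              "T3", "C3", "Cz", "C4", "T4",
              "T5", "P3", "Pz", "P4", "T6",
              "O1", "Oz", "O2"),
    x = c(-0.30, 0.30, -0.80, -0.40, 0.00, 0.40, 0.80,
          -1.00, -0.50, 0.00, 0.50, 1.00,
          -0.80, -0.40, 0.00, 0.40, 0.80,
          -0.30, 0.00, 0.30),
    y = c(1.00, 1.00, 0.60, 0.55, 0.55, 0.55, 0.60,
          0.00, 0.00, 0.00, 0.00, 0.00,
          -0.60, -0.55, -0.55, -0.55, -0.60,
          -1.00, -1.05, -1.00),
    stringsAsFactors = FALSE
  )
  if (n_channels < 2 || n_channels > nrow(full)) {
    stopf("n_channels must be between 2 and %d", nrow(full))
  }
  if (n_channels == nrow(full)) return(full)
  idx <- unique(round(seq(1, nrow(full), length.out = n_channels)))
  # top up if rounding collapsed indices
  k <- 1L
  while (length(idx) < n_channels) {
    if (!(k %in% idx)) idx <- sort(c(idx, k))
    k <- k + 1L
  }
  full[idx, , drop = FALSE]
}

#' Channel adjacency for cluster formation
#'
#' Builds the channel neighbourhood used by the 4-neighbour (edge) connectivity
#' rule: by default consecutive channels in the montage ordering are
#' neighbours. Scalp channels have no canonical linear order, so a custom
#' symmetric logical adjacency matrix can be supplied anywhere the default is
#' accepted.
#'
#' @param n_channels number of channels.
#' @return symmetric logical matrix (`n_channels` x `n_channels`), FALSE on the
#'   diagonal.
#' @export
default_channel_adjacency <- function(n_channels) {
  adj <- matrix(FALSE, n_channels, n_channels)
  if (n_channels > 1) {
    idx <- seq_len(n_channels - 1)
    adj[cbind(idx, idx + 1)] <- TRUE
    adj[cbind(idx + 1, idx)] <- TRUE
  }
  adj
}

# adjacency matrix -> list of integer neighbour vectors (internal)
adjacency_list <- function(adjacency) {
  lapply(seq_len(nrow(adjacency)), function(i) which(adjacency[i, ]))
}

# smooth spatial weighting used by the simulator (internal)
montage_topography <- function(montage, center_x, center_y, spread = 0.6, floor = 0.15) {
  d2 <- (montage$x - center_x)^2 + (montage$y - center_y)^2
  w <- exp(-d2 / (2 * spread^2))
  floor + (1 - floor) * w / max(w)
}
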