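#' Standard 61-channel 10-10 scalp montage
#'
#' Returns the electrode montage assumed throughout the package: 61 scalp
#' positions of the extended 10-10 system (a 64-channel cap recorded against a
#' CPz reference, so CPz itself does not appear as a data channel). Positions
#' are given as flattened 2-D head coordinates on the unit disc (x rightward,
#' y toward the nasion), which is all the spatial detail the Gaussian gain
#' maps of the forward model and the topographic summaries need.
#'
#' @return A data.frame with columns `label`, `x`, `y`, ordered
#'   anterior-to-posterior then left-to-right. This ordering is the canonical
#'   "montage order" used for deterministic tie-breaking.
#' @export
#' @examples
#' m <- standard_montage()
#' nrow(m)                      # 61
#' m[m$label %in% c("Cz", "Oz"), ]
standard_montage <- function() {
  row_def <- list(
    list(y = 0.90, labels = c("Fp1", "Fpz", "Fp2"), span = 0.25),
    list(y = 0.72, labels = c("AF7", "AF3", "AF4", "AF8"), span = 0.50),
    list(y = 0.52, labels = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"),
         span = 0.75),
    list(y = 0.28, labels = c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8"),
         span = 0.85),
    list(y = 0.00, labels = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"),
         span = 0.95),
    # CPz is the reference electrode and carries no data
    list(y = -0.28, labels = c("TP7", "CP5", "CP3", "CP1", "CP2", "CP4", "CP6", "TP8"),
         span = 0.85),
    list(y = -0.52, labels = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8"),
         span = 0.75),
    list(y = -0.72, labels = c("PO7", "PO5", "PO3", "POz", "PO4", "PO6", "PO8"),
         span = 0.50),
    list(y = -0.90, labels = c("O1", "Oz", "O2"), span = 0.25)
  )
  rows <- lapply(row_def, function(r) {
    n <- length(r$labels)
    x <- if (n == 1L) 0 else seq(-r$span, r$span, length.out = n)
    # the CP row omits the midline electrode: spread symmetric, skip 0
    if (identical(r$labels[1], "TP7")) {
      x <- r$span * c(-1, -0.75, -0.5, -0.25, 0.25, 0.5, 0.75, 1)
    }
    data.frame(label = r$labels, x = x, y = r$y, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gaussian electrode gain map
#'
#' Spatial weighting of a neural source across the montage, modelled as an
#' isotropic Gaussian on the flattened head coordinates, max-normalised to 1.
#' Used by the EEG forward model (occipital SSVEP sources centred on Oz,
#' central action-offset source centred on Cz).
#'
#' @param centre electrode label at which the map peaks (must be in the montage).
#' @param sigma Gaussian width in head-radius units (default 0.35).
#' @param montage montage data.frame, see [standard_montage()].
#' @return Named numeric vector of gains in `[0, 1]`, one per channel, max 1.
#' @export
gain_map <- function(centre, sigma = 0.35, montage = standard_montage()) {
  i <- match(centre, montage$label)
  if (is.na(i)) stop("unknown electrode label: ", centre)
  d2 <- (montage$x - montage$x[i])^2 + (montage$y - montage$y[i])^2
  g <- exp(-d2 / (2 * sigma^2))
  g <- g / max(g)
  names(g) <- montage$label
  g
}
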