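#' Electrode montage on the unit sphere
#'
#' Builds an idealized spherical 10/10 montage with 63 scalp electrodes plus
#' the two earlobe reference channels A1/A2. Electrode positions are placed on
#' the unit sphere from their fractional position along the nasion-inion
#' midline and along their coronal arc, the standard idealization used for
#' spherical-spline interpolation. Channel adjacency (used for spatial
#' clustering) connects every pair of scalp electrodes closer than
#' `adj_thresh_rad` great-circle radians.
#'
#' @param n_scalp number of scalp electrodes; only the built-in 63-channel
#'   10/10 table is supported.
#' @param adj_thresh_rad great-circle distance threshold (radians) below which
#'   two scalp electrodes count as neighbours. The default 0.40 rad yields the
#'   typical 10/10 neighbour counts (2--10 per channel) on this layout.
#' @param head_radius_mm scalp radius used to give CSD output physical units.
#' @param seed unused; accepted for interface uniformity with the other
#'   constructors.
#' @return an object of class `montage`: a list with `labels`, `pos` (n x 3
#'   unit vectors, x right / y front / z up), `scalp` (logical, FALSE for
#'   A1/A2), `adjacency` (symmetric logical matrix over all channels, earlobe
#'   rows all FALSE) and `head_radius_mm`.
#' @examples
#' mon <- make_montage()
#' "Oz" %in% mon$labels
#' @export
make_montage <- function(n_scalp = 63, adj_thresh_rad = 0.40,
                         head_radius_mm = 92, seed = NULL) {
  if (n_scalp != 63) {
    stop("only the built-in 63-channel 10/10 label table is supported")
  }
  tab <- montage_table_1010()
  pos <- sph_to_cart(tab$p, tab$q)
  n <- nrow(tab)
  scalp <- !(tab$label %in% c("A1", "A2"))

  # great-circle adjacency among scalp channels only
  d <- tcrossprod(pos)
  d[d > 1] <- 1
  d[d < -1] <- -1
  d <- acos(d)
  adj <- d < adj_thresh_rad
  diag(adj) <- FALSE
  adj[!scalp, ] <- FALSE
  adj[, !scalp] <- FALSE
  dimnames(adj) <- list(tab$label, tab$label)

  structure(list(labels = tab$label, pos = pos, scalp = scalp,
                 adjacency = adj, head_radius_mm = head_radius_mm),
            class = "montage")
}

# Fractional coordinates: p = position along the nasion->inion midline
# (0 = nasion, 0.5 = vertex), q = signed fraction along the coronal arc
# (-1 = left ear, +1 = right ear). Earlobes sit just below the equator.
montage_table_1010 <- function() {
  row <- function(prefix, p, nums, qs) {
    lab <- character(0); q <- numeric(0)
    for (i in seq_along(nums)) {
      n <- nums[i]
      if (is.na(n)) {
        lab <- c(lab, paste0(prefix, "z")); q <- c(q, 0)
      } else {
        lab <- c(lab, paste0(prefix, n))
        q <- c(q, ifelse(n %% 2 == 1, -qs[i], qs[i]))
      }
    }
    data.frame(label = lab, p = p, q = q, stringsAsFactors = FALSE)
  }
  tab <- rbind(
    row("Fp", 0.10, c(1, NA, 2),                c(0.25, 0, 0.25)),
    row("AF", 0.20, c(7, 3, NA, 4, 8),          c(0.8, 0.4, 0, 0.4, 0.8)),
    row("F",  0.30, c(7, 5, 3, 1, NA, 2, 4, 6, 8),
        c(0.8, 0.6, 0.4, 0.2, 0, 0.2, 0.4, 0.6, 0.8)),
    rbind(row("FT", 0.40, c(7), 0.8),
          row("FC", 0.40, c(5, 3, 1, NA, 2, 4, 6), c(0.6, 0.4, 0.2, 0, 0.2, 0.4, 0.6)),
          row("FT", 0.40, c(8), 0.8)),
    rbind(row("T", 0.50, c(7), 0.8),
          row("C", 0.50, c(5, 3, 1, NA, 2, 4, 6), c(0.6, 0.4, 0.2, 0, 0.2, 0.4, 0.6)),
          row("T", 0.50, c(8), 0.8)),
    rbind(row("TP", 0.60, c(9, 7), c(1.0, 0.8)),
          row("CP", 0.60, c(5, 3, 1, NA, 2, 4, 6), c(0.6, 0.4, 0.2, 0, 0.2, 0.4, 0.6)),
          row("TP", 0.60, c(8, 10), c(0.8, 1.0))),
    row("P",  0.70, c(7, 5, 3, 1, NA, 2, 4, 6, 8),
        c(0.8, 0.6, 0.4, 0.2, 0, 0.2, 0.4, 0.6, 0.8)),
    row("PO", 0.80, c(7, 3, NA, 4, 8),          c(0.8, 0.4, 0, 0.4, 0.8)),
    row("O",  0.90, c(1, NA, 2),                c(0.25, 0, 0.25)),
    data.frame(label = c("A1", "A2"), p = 0.55, q = c(-1.15, 1.15),
               stringsAsFactors = FALSE)
  )
  rownames(tab) <- NULL
  tab
}

sph_to_cart <- function(p, q) {
  th_s <- (p - 0.5) * pi      # sagittal angle from vertex, negative = front
  th_l <- q * pi / 2          # lateral angle, positive = right
  cbind(x = sin(th_l),
        y = -cos(th_l) * sin(th_s),
        z = cos(th_l) * cos(th_s))
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %d channels (%d scalp + %d reference), head radius %.0f mm\n",
              length(x$labels), sum(x$scalp), sum(!x$scalp), x$head_radius_mm))
  deg <- rowSums(x$adjacency[x$scalp, x$scalp, drop = FALSE])
  cat(sprintf("  adjacency: %d edges, %d-%d neighbours per scalp channel\n",
              sum(x$adjacency) / 2, min(deg), max(deg)))
  invisible(x)
}

channel_index <- function(montage, channel) {
  i <- match(channel, montage$labels)
  if (anyNA(i)) stop("channel(s) not in montage: ",
                     paste(channel[is.na(i)], collapse = ", "))
  i
}
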