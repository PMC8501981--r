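#' Normalize a locus across supercoiling zones from qPCR delta-Ct values
#'
#' Psoralen-crosslinked genomic DNA separates electrophoretically into five
#' zones, from hyper-negatively supercoiled (zone I) to positively
#' supercoiled (zone V). The qPCR readout per zone is a delta-Ct relative to
#' zone I (whose entry is 0 by convention); the normalized fraction of the
#' locus in zone i is
#' \deqn{f_i = 2^{\Delta Ct(Z_i - Z_1)} / \sum_{j=1}^{5} 2^{\Delta Ct(Z_j - Z_1)}.}
#'
#' Sign convention: a larger delta-Ct means more template in that zone (the
#' zone's amplification leads the reference), so enrichment raises the
#' fraction. qPCR sign conventions vary between instruments; values are
#' re-referenced to the first zone if its entry is non-zero.
#'
#' @param delta_ct numeric vector of exactly 5 finite delta-Ct values
#'   (zones I-V).
#' @return object of class \code{"zone_distribution"}: numeric vector of 5
#'   fractions summing to 1.
#' @examples
#' normalize_zones(c(0, 0, 0, 0, 0))   # all 0.2
#' normalize_zones(c(0, 1, 2, 2, 0))   # 1/12 2/12 4/12 4/12 1/12
#' @export
normalize_zones <- function(delta_ct) {
  delta_ct <- as.numeric(delta_ct)
  if (length(delta_ct) != 5L)
    stop("expected exactly 5 zone delta-Ct values, got ", length(delta_ct))
  if (any(!is.finite(delta_ct))) stop("delta-Ct values must be finite")
  delta_ct <- delta_ct - delta_ct[1L]   # re-reference to zone I
  w <- 2^delta_ct
  f <- w / sum(w)
  names(f) <- paste0("zone_", c("I", "II", "III", "IV", "V"))
  structure(f, class = "zone_distribution")
}

#' @export
print.zone_distribution <- function(x, ...) {
  cat("Zone distribution (fractions):\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Read a zone Ct table from CSV
#'
#' Column layout: \code{locus, zone, delta_ct, replicate}; zones may be
#' labelled I-V or 1-5.
#'
#' @param path CSV path.
#' @return data frame with one row per replicate and one column per zone
#'   fraction after per-replicate normalization, plus \code{locus} and
#'   \code{replicate}.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("locus", "zone", "delta_ct", "replicate")
  if (!all(need %in% names(df)))
    stop("expected columns: ", paste(need, collapse = ", "))
  zmap <- c(I = 1, II = 2, III = 3, IV = 4, V = 5,
            "1" = 1, "2" = 2, "3" = 3, "4" = 4, "5" = 5)
  df$zone_i <- zmap[as.character(df$zone)]
  if (any(is.na(df$zone_i))) stop("unrecognized zone labels")
  out <- list()
  for (key in unique(paste(df$locus, df$replicate, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    sub <- df[df$locus == parts[1L] & df$replicate == parts[2L], ]
    sub <- sub[order(sub$zone_i), ]
    f <- normalize_zones(sub$delta_ct)
    out[[key]] <- data.frame(locus = parts[1L], replicate = parts[2L],
                             t(unclass(f)), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## mean zone index sum(i * f_i) of one normalized distribution
mean_zone_index <- function(fractions) {
  sum(seq_len(5L) * as.numeric(fractions))
}

#' Permutation test for a zone-distribution shift between conditions
#'
#' Per-replicate distributions are summarized by the mean zone index
#' \eqn{\sum_i i f_i} (low under zone-I enrichment, high under zone-V
#' enrichment). The statistic is the difference of condition means
#' (a minus b); a two-tailed p-value is obtained by permuting condition
#' labels, with the add-one convention so the attainable floor is
#' \code{1 / (n_perm + 1)}.
#'
#' @param dist_a,dist_b matrices (or data frames) of replicate zone
#'   fractions, one row per replicate, 5 columns (>= 3 replicates each).
#' @param n_perm number of label permutations.
#' @param rng_seed integer seed.
#' @return object of class \code{"zone_shift_test"}: list with
#'   \code{statistic} (difference in mean zone index), \code{p_value},
#'   \code{n_perm}.
#' @export
zone_shift_test <- function(dist_a, dist_b, n_perm = 10000L, rng_seed = 1L) {
  a <- as.matrix(dist_a); b <- as.matrix(dist_b)
  if (ncol(a) != 5L || ncol(b) != 5L) stop("expected 5 zone columns")
  if (nrow(a) < 3L || nrow(b) < 3L)
    stop("need >= 3 replicates per condition")
  mz_a <- apply(a, 1L, mean_zone_index)
  mz_b <- apply(b, 1L, mean_zone_index)
  obs <- mean(mz_a) - mean(mz_b)
  pool <- c(mz_a, mz_b)
  na <- length(mz_a)
  set.seed(as.integer(rng_seed))
  perm <- replicate(n_perm, {
    idx <- sample.int(length(pool), na)
    mean(pool[idx]) - mean(pool[-idx])
  })
  p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  structure(list(statistic = obs, p_value = p, n_perm = n_perm,
                 n_a = na, n_b = length(mz_b)),
            class = "zone_shift_test")
}

#' @export
print.zone_shift_test <- function(x, ...) {
  cat(sprintf(
    "Zone shift test: mean-zone-index difference %.4f, two-tailed p = %.4g (%d permutations)\n",
    x$statistic, x$p_value, x$n_perm))
  invisible(x)
}

#' Write zone fractions or a shift-test result to JSON
#'
#' @param x a \code{zone_distribution} or \code{zone_shift_test}.
#' @param path output path.
#' @export
write_zone_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
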