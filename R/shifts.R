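# Chemical-shift comparison: predicted per-frame shifts (from an external
# predictor such as SPARTA+) are aggregated over frames and replicates and
# compared with experimental shifts under the combined-error criterion.

.shift_nuclei <- c("15N", "1HN")

#' Default predictor uncertainties in ppm
#'
#' The reported prediction errors of the SPARTA+ backbone-shift predictor:
#' 0.49 ppm for 1HN and 2.45 ppm for 15N.
#' @return named numeric vector in ppm.
#' @export
default_eps_pred <- function() c("1HN" = 0.49, "15N" = 2.45)

#' Aggregate per-frame predicted chemical shifts
#'
#' Two-level average matching the replicate structure of the simulations:
#' mean shift per residue/nucleus within each replicate, then mean across
#' replicates; `eps_sim` is the SEM across replicate means.  Residues (or
#' nuclei) absent from some replicate are dropped with a warning.
#'
#' @param tables list (one element per replicate) of data.frames with
#'   columns `frame`, `residue`, `nucleus`, `delta` (ppm).
#' @return data.frame with `residue`, `nucleus`, `delta_sim`, `eps_sim`,
#'   `n_replicates`.
#' @export
aggregate_predicted_shifts <- function(tables) {
  stopifnot(length(tables) >= 1)
  per_rep <- lapply(tables, function(tb) {
    stopifnot(all(c("residue", "nucleus", "delta") %in% names(tb)))
    bad <- setdiff(unique(tb$nucleus), .shift_nuclei)
    if (length(bad))
      stop("nucleus not in {15N, 1HN}: ", paste(bad, collapse = ", "))
    agg <- stats::aggregate(delta ~ residue + nucleus, data = tb, FUN = mean)
    agg
  })
  key <- function(df) paste(df$residue, df$nucleus)
  keys <- lapply(per_rep, key)
  common <- Reduce(intersect, keys)
  all_keys <- unique(unlist(keys))
  dropped <- setdiff(all_keys, common)
  if (length(dropped))
    warning("dropped ", length(dropped),
            " residue/nucleus record(s) missing from some replicate: ",
            paste(utils::head(dropped, 5), collapse = "; "),
            if (length(dropped) > 5) " ..." else "")
  n <- length(per_rep)
  mat <- vapply(per_rep, function(df)
    df$delta[match(common, key(df))], numeric(length(common)))
  mat <- matrix(mat, nrow = length(common))
  first <- per_rep[[1]][match(common, keys[[1]]), ]
  data.frame(residue = first$residue, nucleus = first$nucleus,
             delta_sim = rowMeans(mat),
             eps_sim = if (n > 1) apply(mat, 1, stats::sd) / sqrt(n)
                       else rep(0, length(common)),
             n_replicates = n)
}

#' Compare simulated and experimental chemical shifts
#'
#' Per residue and nucleus: `delta_delta = delta_sim - delta_exp`, combined
#' error `eps = sqrt(eps_sim^2 + eps_pred^2)` (the experimental shift error
#' does not enter the criterion), and the overlap flag
#' `|delta_delta| <= eps` (the boundary counts as overlap: the interval
#' `delta_delta +- eps` still touches zero).
#'
#' @param sim data.frame from [aggregate_predicted_shifts] (columns
#'   `residue`, `nucleus`, `delta_sim`, `eps_sim`).
#' @param exp_table data.frame with `residue`, `nucleus`, `delta_exp` (ppm).
#' @param eps_pred named vector of predictor uncertainties per nucleus in
#'   ppm (default [default_eps_pred]).
#' @return data.frame of shift records with `delta_delta`, `eps`,
#'   `eps_ratio` (`eps_sim/eps_pred`) and logical `overlap`.
#' @export
compare_shifts <- function(sim, exp_table, eps_pred = default_eps_pred()) {
  bad <- setdiff(unique(c(sim$nucleus, exp_table$nucleus)), .shift_nuclei)
  if (length(bad))
    stop("nucleus not in {15N, 1HN}: ", paste(bad, collapse = ", "))
  merged <- merge(sim, exp_table, by = c("residue", "nucleus"))
  ep <- unname(eps_pred[merged$nucleus])
  delta_delta <- merged$delta_sim - merged$delta_exp
  eps <- sqrt(merged$eps_sim^2 + ep^2)
  out <- data.frame(residue = merged$residue, nucleus = merged$nucleus,
                    delta_sim = merged$delta_sim,
                    delta_exp = merged$delta_exp,
                    eps_sim = merged$eps_sim, eps_pred = ep,
                    delta_delta = delta_delta, eps = eps,
                    eps_ratio = merged$eps_sim / ep,
                    # small relative guard so exact-boundary cases are not
                    # lost to floating-point representation
                    overlap = abs(delta_delta) <= eps * (1 + 1e-12) + 1e-12)
  out[order(out$nucleus, out$residue), ]
}
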