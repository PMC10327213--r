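# Whole-structure driver: per-residue building, segment assembly,
# relabeling and occupancy culling.

#' Build a multiconformer model for a whole structure
#'
#' Runs [build_residue()] on every residue (residues are independent; any
#' execution order gives identical output), then reconnects the chain:
#' segment identification and occupancy harmonization, Monte Carlo altloc
#' relabeling, and low-occupancy culling with renormalization.
#'
#' @param structure input `mc_structure` (typically single-conformer).
#' @param grid a [density_grid()].
#' @param config a [build_config()].
#' @param seed relabeling seed.
#' @param assemble run segment optimization + relabeling (default `TRUE`).
#' @param cull cull occupancies below `cull_cutoff` and renormalize.
#' @param cull_cutoff occupancy cutoff (default 0.10).
#' @return The built `mc_structure`; attribute `"log"` holds a per-residue
#'   data.frame (conformer counts, rss, BIC, occupancy sums, skips).
#' @export
build_multiconformer <- function(structure, grid, config, seed = 0L,
                                 assemble = TRUE, cull = TRUE,
                                 cull_cutoff = 0.10) {
  built <- structure
  logs <- list()
  for (i in seq_along(structure$residues)) {
    res <- build_residue(structure$residues[[i]], grid, config)
    lg <- attr(res, "log")
    if (is.null(lg)) {
      r0 <- structure$residues[[i]]
      lg <- data.frame(chain = r0$chain, resno = r0$resno, resn = r0$resn,
                       n_conformers = length(r0$conformers),
                       rss = NA_real_, bic = NA_real_, occ_sum = NA_real_)
      lg$skipped <- attr(res, "skipped")
    } else {
      lg$skipped <- NA_character_
    }
    logs[[i]] <- lg
    attr(res, "log") <- NULL
    built$residues[[i]] <- res
  }
  if (assemble) {
    segs <- identify_segments(built)
    for (seg in segs)
      built <- optimize_segment(built, seg, grid, config)
    built <- relabel_altlocs(built, seed = seed)
  }
  if (cull) built <- cull_low_occupancy(built, cull_cutoff)
  attr(built, "log") <- do.call(rbind, logs)
  built
}
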