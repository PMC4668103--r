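#' Total-quantity ppm normalization of per-gel spot intensities
#'
#' Each physical gel corresponds to one (genotype, stage, replicate)
#' combination. Every spot intensity on a gel is divided by the total
#' intensity of all valid spots on that gel and multiplied by `ppm_scale`,
#' so that after normalization each gel sums exactly to `ppm_scale`
#' (parts per million of total spot volume by default). This makes gels
#' with different overall staining or loading directly comparable; any
#' uniform rescaling of a single gel leaves its normalized values
#' unchanged.
#'
#' "Valid spots" are all spots present in the table for the gel; spot
#' detection and matching happen upstream and are out of scope here.
#'
#' @param table a `spot_table` (see [read_spot_table()]).
#' @param ppm_scale positive normalization constant, default `1e6`.
#' @return A `normalized_spot_table` with the same rows and row order,
#'   intensities replaced by their ppm values.
#' @examples
#' tab <- validate_spot_table(data.frame(
#'   spot_id = c("s1", "s2", "s3"), genotype = "A", stage = "D8",
#'   replicate = 1L, intensity = c(2, 3, 5)), expected_replicates = NULL)
#' normalize_total_ppm(tab)$intensity  # 2e5 3e5 5e5
#' @export
normalize_total_ppm <- function(table, ppm_scale = 1e6) {
  stopifnot(is.data.frame(table))
  stopifnot(is.numeric(ppm_scale), length(ppm_scale) == 1L, ppm_scale > 0)
  need <- c("spot_id", "genotype", "stage", "replicate", "intensity")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  gel <- paste(table$genotype, table$stage, table$replicate, sep = "/")
  totals <- tapply(table$intensity, gel, sum)
  degenerate <- names(totals)[totals <= 0]
  if (length(degenerate))
    stop("degenerate gel(s) with zero total intensity: ",
         paste(degenerate, collapse = ", "))
  out <- as.data.frame(table)
  out$intensity <- table$intensity / as.vector(totals[gel]) * ppm_scale
  class(out) <- c("normalized_spot_table", "spot_table", "data.frame")
  out
}
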