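# Shared fixture builders for the suite: everything is generated in code.

# minimal complete long table: genotypes x stages x replicates per spot
make_spot_table <- function(genotypes = c("P1", "P2", "F1"),
                            stages = c("D8", "D10"), n_rep = 3,
                            spots = c("s1", "s2"), intensity = NULL) {
  grid <- expand.grid(replicate = seq_len(n_rep), stage = stages,
                      genotype = genotypes, spot_id = spots,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$intensity <- if (is.null(intensity)) {
    seq_len(nrow(grid)) + 10
  } else intensity
  validate_spot_table(grid[, c("spot_id", "genotype", "stage",
                               "replicate", "intensity")],
                      expected_replicates = n_rep)
}

write_tsv_fixture <- function(df, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  write_report(df, path)
  path
}

# one-spot triad table from explicit replicate vectors
triad_table_from_reps <- function(p1, p2, f1, stage = "D10",
                                  spot = "s1") {
  df <- rbind(
    data.frame(spot_id = spot, genotype = "P1", stage = stage,
               replicate = seq_along(p1), intensity = p1),
    data.frame(spot_id = spot, genotype = "P2", stage = stage,
               replicate = seq_along(p2), intensity = p2),
    data.frame(spot_id = spot, genotype = "F1", stage = stage,
               replicate = seq_along(f1), intensity = f1))
  validate_spot_table(df, expected_replicates = NULL)
}

default_triad <- function(stage = "D10") {
  triad_design("F1", "P1", "P2", stage)
}
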