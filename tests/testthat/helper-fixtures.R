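## Minimal tree-level data.frame with valid defaults; override via ...
makeTrees <- function(n, ...) {
  df <- data.frame(
    tree_id = sprintf("T%03d", seq_len(n)),
    water_group = "drought", drought_stratum = "mild",
    girdled = FALSE, inoculated = FALSE,
    psi_pd = -2, osmolality = 800, chamber_temp = 305,
    mst_pre = 30, mst_post = 30,
    starch_pre = 0.1, sucrose_pre = 3, glucose_pre = 1, fructose_pre = 1,
    starch_post = 0.1, sucrose_post = 3, glucose_post = 1, fructose_post = 1,
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  df
}

## Cohort of girdled-only trees realizing given (psi, relative loss) pairs
makeLossCohort <- function(psi, relLoss, mstPre = 20) {
  n <- length(psi)
  trees <- makeTrees(n, girdled = TRUE, psi_pd = psi,
                     mst_pre = mstPre, mst_post = mstPre * (1 + relLoss))
  DefenseCohort(trees)
}
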