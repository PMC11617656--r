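#' Construct a DefenseCohort
#'
#' Assembles a [DefenseCohort-class] from a tree-level data.frame and
#' optional pre/post terpene concentration matrices (compounds x trees,
#' mg g^-1 DW). When no matrices are supplied, zero-compound placeholders
#' are used so the tree-level pipeline still runs.
#'
#' @param trees data.frame with the required tree-level columns (see
#'   [DefenseCohort-class])
#' @param terpenesPre,terpenesPost numeric matrices, compounds x trees, with
#'   column names matching `trees$tree_id`
#' @param metadata list of provenance metadata (seed, generator parameters,
#'   file paths)
#' @return a validated `DefenseCohort`
#' @export
DefenseCohort <- function(trees, terpenesPre = NULL, terpenesPost = NULL,
                          metadata = list()) {
  trees <- as.data.frame(trees)
  miss <- setdiff(.REQUIRED_TREE_COLS, colnames(trees))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  n <- nrow(trees)
  if (is.null(terpenesPre))
    terpenesPre <- matrix(numeric(0), nrow = 0, ncol = n,
                          dimnames = list(NULL, trees$tree_id))
  if (is.null(terpenesPost))
    terpenesPost <- matrix(NA_real_, nrow = nrow(terpenesPre), ncol = n,
                           dimnames = dimnames(terpenesPre))
  terpenesPre <- as.matrix(terpenesPre)
  terpenesPost <- as.matrix(terpenesPost)
  if (!identical(colnames(terpenesPre), as.character(trees$tree_id)) ||
      !identical(colnames(terpenesPost), as.character(trees$tree_id)))
    stop("terpene matrix columns must match trees$tree_id in order")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(terpenes_pre = terpenesPre,
                                   terpenes_post = terpenesPost),
    colData = S4Vectors::DataFrame(trees, row.names = trees$tree_id),
    metadata = metadata)
  methods::validObject(out <- methods::new("DefenseCohort", se))
  out
}

#' Treatment cell labels
#'
#' Derives the four-level treatment factor (C, G, I, IG) from the girdle and
#' inoculation flags.
#'
#' @param x a `DefenseCohort` or a data.frame with `girdled` and `inoculated`
#' @return factor with levels C, G, I, IG
#' @export
treatmentCell <- function(x) {
  if (methods::is(x, "DefenseCohort")) x <- treeData(x)
  factor(ifelse(x$girdled,
                ifelse(x$inoculated, "IG", "G"),
                ifelse(x$inoculated, "I", "C")),
         levels = c("C", "G", "I", "IG"))
}

#' Unit conversion between percent dry weight and mg per g dry weight
#'
#' 1 % DW corresponds to 10 mg g^-1 DW. These two helpers are the only
#' place that conversion happens in the package.
#'
#' @param x numeric vector
#' @return converted vector
#' @export
pctToMgPerG <- function(x) 10 * x

#' @rdname pctToMgPerG
#' @export
mgPerGToPct <- function(x) x / 10

#' Total mono+sesquiterpene concentration of a profile
#'
#' Sums per-compound concentrations. Accepts a numeric vector (one profile)
#' or a compounds x trees matrix (returns per-tree totals).
#'
#' @param x numeric vector or matrix of concentrations (mg g^-1 DW, >= 0)
#' @return numeric total(s), mg g^-1 DW
#' @export
totalMST <- function(x) {
  if (any(x < 0, na.rm = TRUE))
    stop("negative compound concentration")
  if (is.matrix(x)) colSums(x) else sum(x)
}

#' Relative terpene composition
#'
#' Scales each profile to sum to one. Profiles are columns of a compounds x
#' trees matrix (or a single numeric vector).
#'
#' @param x numeric vector or matrix of concentrations (>= 0)
#' @return vector or matrix of relative abundances
#' @export
relativeComposition <- function(x) {
  if (is.matrix(x)) {
    tot <- colSums(x)
    if (any(tot <= 0, na.rm = TRUE))
      stop("profile with zero total has no relative composition")
    sweep(x, 2, tot, "/")
  } else {
    if (sum(x) <= 0) stop("profile with zero total has no relative composition")
    x / sum(x)
  }
}

#' Total NSC and soluble-sugar pools
#'
#' Total NSC is starch + sucrose + glucose + fructose (% DW); the soluble
#' sugar pool excludes starch.
#'
#' @param x a `DefenseCohort` or a tree-level data.frame
#' @param when `"pre"` or `"post"` inoculation
#' @param pool `"total"` (all four fractions) or `"sugar"` (no starch)
#' @return numeric vector, % DW, named by tree_id
#' @export
nscPool <- function(x, when = c("pre", "post"), pool = c("total", "sugar")) {
  when <- match.arg(when)
  pool <- match.arg(pool)
  if (methods::is(x, "DefenseCohort")) x <- treeData(x)
  comps <- c("sucrose", "glucose", "fructose")
  if (pool == "total") comps <- c("starch", comps)
  out <- rowSums(as.matrix(x[, paste0(comps, "_", when), drop = FALSE]))
  names(out) <- x$tree_id
  out
}

.cohort_numeric_cols <- function()
  setdiff(.REQUIRED_TREE_COLS,
          c("tree_id", "water_group", "drought_stratum", "girdled", "inoculated"))

#' Read a cohort from CSV files
#'
#' Reads a tree-level `cohort.csv` plus optional wide terpene matrices
#' (`terpenes_pre.csv`, `terpenes_post.csv`; first column `tree_id`, one
#' column per compound). Rows with missing `mst_post` are retained and can
#' be identified by `is.na(mst_post)`; they are excluded from post-tissue
#' analyses downstream, never zero-filled.
#'
#' @param path path to the tree-level CSV
#' @param terpenesPre,terpenesPost optional paths to wide terpene CSVs
#' @param schemaVersion schema identifier (currently `"1.0"`)
#' @return a validated [DefenseCohort-class]
#' @export
readCohort <- function(path, terpenesPre = NULL, terpenesPost = NULL,
                       schemaVersion = "1.0") {
  if (!identical(schemaVersion, "1.0"))
    stop("unknown schema version: ", schemaVersion)
  trees <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.REQUIRED_TREE_COLS, colnames(trees))
  if (length(miss))
    stop("schema error: cohort file lacks column(s): ",
         paste(miss, collapse = ", "))
  for (col in c("girdled", "inoculated")) trees[[col]] <- as.logical(trees[[col]])
  readWide <- function(p) {
    if (is.null(p)) return(NULL)
    w <- utils::read.csv(p, stringsAsFactors = FALSE, check.names = FALSE)
    if (colnames(w)[1] != "tree_id")
      stop("schema error: terpene file must start with a tree_id column")
    m <- t(as.matrix(w[, -1, drop = FALSE]))
    colnames(m) <- w$tree_id
    m[, as.character(trees$tree_id), drop = FALSE]
  }
  DefenseCohort(trees, readWide(terpenesPre), readWide(terpenesPost),
                metadata = list(source = path, schema_version = schemaVersion))
}

#' Write a cohort to CSV files
#'
#' Inverse of [readCohort()]: writes `cohort.csv` and, when compound
#' profiles are present, `terpenes_pre.csv` / `terpenes_post.csv` into
#' `dir`. Numeric fields are written with full precision so a read/write
#' round trip reproduces the cohort.
#'
#' @param cohort a `DefenseCohort`
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  trees <- treeData(cohort)
  paths <- file.path(dir, "cohort.csv")
  .write_csv(trees, paths)
  if (nrow(cohort) > 0) {
    for (when in c("pre", "post")) {
      m <- terpenes(cohort, when)
      w <- data.frame(tree_id = colnames(m), t(m), check.names = FALSE)
      p <- file.path(dir, sprintf("terpenes_%s.csv", when))
      .write_csv(w, p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

## full-precision, locale-independent CSV writer (deterministic bytes)
.write_csv <- function(df, path) {
  for (col in names(df))
    if (is.numeric(df[[col]]))
      df[[col]] <- vapply(df[[col]], function(v)
        if (is.na(v)) "" else format(v, digits = 17, scientific = FALSE,
                                     trim = TRUE),
        character(1))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
}

#' Write pipeline result tables with a checksum manifest
#'
#' Writes the per-tree induction, stoichiometric-budget and water-state
#' tables as CSV, the model summaries as JSON, and a `manifest.json`
#' listing each file with its MD5 checksum. Re-running on identical inputs
#' produces byte-identical files.
#'
#' @param results named list with elements `induction`, `stoichiometry`,
#'   `water_state` (data.frames, may be empty) and `models` (list)
#' @param outDir output directory
#' @return the manifest, invisibly (data.frame of file, md5)
#' @export
writeResults <- function(results, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in c("induction", "stoichiometry", "water_state")) {
    if (is.null(results[[nm]])) next
    p <- file.path(outDir, paste0(nm, ".csv"))
    .write_csv(as.data.frame(results[[nm]]), p)
    files <- c(files, p)
  }
  if (!is.null(results$models)) {
    p <- file.path(outDir, "models.json")
    jsonlite::write_json(results$models, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    files <- c(files, p)
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       pretty = TRUE)
  invisible(manifest)
}
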