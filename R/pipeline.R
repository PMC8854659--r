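## End-to-end orchestration over a scenario directory (or equivalent real
## inputs): split -> attach -> test -> FDR -> call -> annotate -> enrich,
## with a JSON run manifest recording seeds, parameter values, filter
## counts, and file digests so identical inputs reproduce identical output.

#' Locate the standard input files of a scenario directory
#'
#' @param dir directory produced by [generate_scenario()] (or laid out the
#'   same way: `neutral.mod`, `aln.maf`, `conserved.bed`, `genes.bed12`,
#'   `lists/*.txt`, optional `scenario.json`).
#' @return named list of paths (missing optional entries are NA).
#' @export
scenario_files <- function(dir) {
  p <- function(...) {
    f <- file.path(dir, ...)
    if (file.exists(f)) f else NA_character_
  }
  lists <- list.files(file.path(dir, "lists"), pattern = "\\.txt$",
                      full.names = TRUE)
  list(mod = p("neutral.mod"), maf = p("aln.maf"), bed = p("conserved.bed"),
       genes = p("genes.bed12"), lists = lists, config = p("scenario.json"),
       truth = p("truth.tsv"))
}

#' Run the full accelerated-region analysis
#'
#' @param dir scenario directory (see [scenario_files()]).
#' @param out_dir output directory.
#' @param branches `"leaf"` (target species alone) or `"subtree"` (target
#'   plus sister); resolved to leaf names via `scenario.json` unless
#'   `subtree_leaves` is given.
#' @param subtree_leaves explicit tested leaf set (overrides `branches`).
#' @param ref reference species (default from `scenario.json`).
#' @param nsims simulations per stratum null.
#' @param width tile width, bp.
#' @param flank gene-assignment flank, bp.
#' @param q_call FDR threshold for AR calls.
#' @param q_candidate relaxed threshold for candidate ARs.
#' @param min_species minimum species present per tile.
#' @param seed master seed.
#' @return invisible list: `results`, `ars`, `candidates`, `assignments`,
#'   `enrichment` (list of `enrichment_result`), `manifest`, `files`.
#' @export
run_pipeline <- function(dir, out_dir, branches = c("leaf", "subtree"),
                         subtree_leaves = NULL, ref = NULL,
                         nsims = 100000L, width = 50L, flank = 10000L,
                         q_call = 0.05, q_candidate = 0.1,
                         min_species = 3L, seed = 1L) {
  branches <- match.arg(branches)
  t0 <- Sys.time()
  inp <- scenario_files(dir)
  for (k in c("mod", "maf", "bed", "genes"))
    if (is.na(inp[[k]])) stop("missing input file: ", k, " in ", dir, call. = FALSE)
  cf <- if (!is.na(inp$config)) read_scenario_config(inp$config) else NULL
  if (is.null(subtree_leaves)) {
    if (is.null(cf))
      stop("no scenario.json: pass subtree_leaves explicitly", call. = FALSE)
    subtree_leaves <- if (branches == "leaf") cf$target else cf$subtree
  }
  if (is.null(ref)) {
    if (is.null(cf)) stop("no scenario.json: pass ref explicitly", call. = FALSE)
    ref <- cf$ref
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  logmsg <- function(...) cat(format(Sys.time(), "%H:%M:%S "), sprintf(...),
                              "\n", sep = "", file = logf, append = TRUE)
  cat("", file = logf)
  logmsg("run-all: branches=%s subtree={%s} nsims=%d width=%d flank=%d q_call=%g q_candidate=%g min_species=%d seed=%d",
         branches, paste(subtree_leaves, collapse = ","), nsims, width, flank,
         q_call, q_candidate, min_species, seed)

  model <- read_mod(inp$mod)
  elements <- read_bed(inp$bed)
  tiles <- split_elements(elements, width)
  logmsg("split: %d elements -> %d tiles of %d bp", nrow(elements),
         nrow(tiles), width)
  att <- attach_alignments(tiles, inp$maf, model, ref,
                           min_species = min_species,
                           subtree = subtree_leaves)
  logmsg("attach: %d tiles retained, %d excluded (presence filter)",
         length(att$tiles), att$n_excluded)
  tst <- test_elements(model, att, subtree_leaves, n_sims = nsims, seed = seed)
  res <- tst$results
  logmsg("test: %d tiles tested in %d strata; %d flagged (optimizer)",
         nrow(res), length(tst$nulls), length(tst$flagged))
  ars <- call_ars(res, q_call)
  cand <- candidate_ars(res, q_candidate)
  logmsg("calls: %d ARs at q<%g; %d candidates at q<%g", nrow(ars), q_call,
         nrow(cand), q_candidate)

  genes <- read_genes(inp$genes)
  asn <- map_elements_to_genes(ars, genes, flank)
  ug <- unique_genes(asn)
  logmsg("annotate: %d assignments, %d unique genes within %d bp",
         nrow(asn), ug$n, flank)

  enr <- list()
  for (lf in inp$lists) {
    nm <- sub("\\.txt$", "", basename(lf))
    gl <- read_gene_list(lf)
    ql <- suppressWarnings(elements_for_gene_list(res, gl, genes, flank))
    if (length(ql) >= 2) {
      enr[[nm]] <- fdr_shift_test(ql, res$q_fdr, name = nm)
      logmsg("enrich %s: n=%d mean q %.4f vs %.4f, t=%.3f df=%.2f p=%.4g",
             nm, enr[[nm]]$n_list, enr[[nm]]$mean_q_list,
             enr[[nm]]$mean_q_background, enr[[nm]]$t, enr[[nm]]$df,
             enr[[nm]]$p)
    } else logmsg("enrich %s: skipped (%d elements)", nm, length(ql))
  }

  files <- c(results = file.path(out_dir, "results.tsv"),
             ars = file.path(out_dir, "ars.bed"),
             candidates = file.path(out_dir, "candidates.bed"),
             assignments = file.path(out_dir, "assignments.tsv"),
             enrichment = file.path(out_dir, "enrichment.tsv"),
             manifest = file.path(out_dir, "manifest.json"))
  write_results_tsv(res, files["results"])
  write_ar_bed(ars, files["ars"])
  write_ar_bed(cand, files["candidates"])
  write.table(asn, files["assignments"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (length(enr)) write_enrichment_tsv(enr, files["enrichment"])

  params <- list(branches = branches, subtree = subtree_leaves, ref = ref,
                 nsims = nsims, width = width, flank = flank, q_call = q_call,
                 q_candidate = q_candidate, min_species = min_species,
                 seed = seed)
  manifest <- list(
    package = as.character(utils::packageVersion("arscan")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    params = params,
    config_hash = hash_object(params),
    seed = seed,
    inputs = file_digests(unlist(inp[c("mod", "maf", "bed", "genes")],
                                 use.names = TRUE)),
    counts = list(elements = nrow(elements), tiles = nrow(tiles),
                  retained = length(att$tiles), excluded = att$n_excluded,
                  flagged = length(tst$flagged), tested = nrow(res),
                  strata = length(tst$nulls), ars = nrow(ars),
                  candidates = nrow(cand), assignments = nrow(asn),
                  unique_genes = ug$n),
    outputs = file_digests(files[file.exists(files)]),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, files["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  logmsg("done in %.1f s", manifest$elapsed_sec)
  invisible(list(results = res, ars = ars, candidates = cand,
                 assignments = asn, enrichment = enr, manifest = manifest,
                 files = files, nulls = tst$nulls))
}

## md5 of the canonical JSON serialization of an R object
hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

file_digests <- function(paths) {
  paths <- paths[!is.na(paths)]
  as.list(tools::md5sum(paths))
}
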