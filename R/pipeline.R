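#' Pipeline run configuration
#'
#' Flat key = value configuration driving [run_extract()] and
#' [run_pipeline()] (and mirrored by the command-line flags of the
#' `topotier` script). Unknown keys are rejected.
#'
#' @param in_dir input directory of structure files.
#' @param out_dir output directory (created if missing).
#' @param boundaries tier boundaries (numeric, default `c(-0.1, 0.1)`).
#' @param min_atoms,max_atoms ligand size filter (defaults 10, 485).
#' @param pocket_mode `"none"`, `"residue_complete"` or `"atom_level"`.
#' @param pocket_cutoff pocket cutoff in Angstrom (`NULL` = mode default).
#' @param top_k search/matrix truncation (default 100).
#' @param fractions EF percent fractions (default `c(1.0, 0.25)`).
#' @param charge_mode `"input"` (use file charges, assign only when absent)
#'   or `"gasteiger"` (always reassign).
#' @param seed integer seed for any stochastic step.
#' @param verbosity 0 (quiet), 1 (stage counts) or 2 (per molecule).
#' @return object of class `run_config`.
#' @export
run_config <- function(in_dir = ".", out_dir = "topotier_out",
                       boundaries = c(-0.1, 0.1), min_atoms = 10L,
                       max_atoms = 485L,
                       pocket_mode = c("none", "residue_complete",
                                       "atom_level"),
                       pocket_cutoff = NULL, top_k = 100L,
                       fractions = c(1.0, 0.25),
                       charge_mode = c("input", "gasteiger"), seed = 1L,
                       verbosity = 1L) {
  pocket_mode <- match.arg(pocket_mode)
  charge_mode <- match.arg(charge_mode)
  if (min_atoms > max_atoms) {
    stop("run_config(): min_atoms (", min_atoms, ") exceeds max_atoms (",
         max_atoms, ")")
  }
  structure(list(in_dir = in_dir, out_dir = out_dir,
                 boundaries = as.numeric(boundaries),
                 min_atoms = as.integer(min_atoms),
                 max_atoms = as.integer(max_atoms),
                 pocket_mode = pocket_mode, pocket_cutoff = pocket_cutoff,
                 top_k = as.integer(top_k), fractions = as.numeric(fractions),
                 charge_mode = charge_mode, seed = as.integer(seed),
                 verbosity = as.integer(verbosity)),
            class = "run_config")
}

#' Read / write a run configuration as flat key=value text
#' @param path config file path.
#' @return a [run_config()] (for `read_run_config`).
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="),
                        character(1)))
  args <- list()
  for (i in seq_along(keys)) {
    v <- vals[i]
    if (!nzchar(v)) next
    args[[keys[i]]] <- switch(keys[i],
      boundaries = , fractions = as.numeric(strsplit(v, ",")[[1]]),
      min_atoms = , max_atoms = , top_k = , seed = ,
      verbosity = as.integer(v),
      pocket_cutoff = as.numeric(v),
      v)
  }
  do.call(run_config, args)
}

#' @rdname read_run_config
#' @param config a [run_config()].
#' @export
write_run_config <- function(config, path) {
  keys <- names(unclass(config))
  keys <- keys[!vapply(unclass(config), is.null, logical(1))]
  writeLines(c("# topotier run configuration",
               vapply(keys, function(k) {
                 paste0(k, "=", paste(config[[k]], collapse = ","))
               }, character(1))), path)
  invisible(path)
}

config_hash <- function(config) {
  # hash only the analysis parameters, not io paths/verbosity, so reruns of
  # the same analysis into different directories share a hash
  sci <- c("boundaries", "min_atoms", "max_atoms", "pocket_mode",
           "pocket_cutoff", "top_k", "fractions", "charge_mode", "seed")
  s <- paste(vapply(unclass(config)[sci],
                    function(v) paste(v, collapse = ","),
                    character(1)), collapse = "|")
  # small rolling hash; stability across sessions is all that is needed
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

output_header <- function(config, scheme) {
  sprintf("# topotier %s; scheme=%s; config=%s",
          as.character(utils::packageVersion("topotier")),
          scheme_signature(scheme), config_hash(config))
}

log_stage <- function(config, ...) {
  if (config$verbosity >= 1) message(sprintf(...))
}

#' Extract, filter and (optionally) pocket-annotate an input directory
#'
#' Parses every structure file under `config$in_dir`, splits entries into
#' molecules, strips metal cores, applies the ligand size filters and
#' writes each surviving hetero molecule as a PDB file plus a manifest TSV
#' (entry, mol_id, n_atoms, kept or discard reason). When a pocket mode is
#' configured, a pocket file is written next to each kept ligand.
#'
#' @param config a [run_config()].
#' @return the manifest data.frame, invisibly.
#' @export
run_extract <- function(config) {
  files <- list.files(config$in_dir, pattern = "\\.(pdb|ent|mol2|pqr)$",
                      full.names = TRUE, ignore.case = TRUE)
  if (!length(files)) stop("run_extract(): no structure files in ", config$in_dir)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  scheme <- tier_scheme(config$boundaries)
  manifest <- list(); n_failed <- 0L
  for (f in files) {
    entry <- tools::file_path_sans_ext(basename(f))
    mols <- tryCatch(parse_structure(f), error = function(e) {
      message("run_extract(): skipping ", f, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(mols)) { n_failed <- n_failed + 1L; next }
    all_atoms <- do.call(rbind, lapply(mols, as.data.frame))
    het <- Filter(function(m) all(m$atoms$record_kind == "hetero"), mols)
    for (mol in het) {
      mol <- strip_metal_atoms(mol)
      n <- n_atoms(mol)
      status <- if (n < config$min_atoms) {
        sprintf("size<%d", config$min_atoms)
      } else if (n > config$max_atoms) {
        sprintf("size>%d", config$max_atoms)
      } else "kept"
      manifest[[length(manifest) + 1L]] <- data.frame(
        entry = entry, mol_id = mol$mol_id, n_atoms = n, status = status,
        stringsAsFactors = FALSE)
      if (status != "kept") next
      write_structure(mol, file.path(config$out_dir,
                                     paste0(mol$mol_id, ".pdb")), "pdb")
      if (config$pocket_mode != "none") {
        spec <- pocket_spec(config$pocket_mode, config$pocket_cutoff)
        pk <- extract_pocket(all_atoms, mol, spec)
        if (n_atoms(pk) > 0) {
          write_structure(pk, file.path(config$out_dir,
                                        sprintf("%s_%s%g.pdb", mol$mol_id,
                                                spec$mode, spec$cutoff)),
                          "pdb")
        }
      }
    }
  }
  if (n_failed == length(files)) stop("run_extract(): all input entries failed to parse")
  manifest <- if (length(manifest)) {
    do.call(rbind, manifest)
  } else {
    data.frame(entry = character(), mol_id = character(),
               n_atoms = integer(), status = character())
  }
  mpath <- file.path(config$out_dir, "manifest.tsv")
  con <- file(mpath, "w")
  writeLines(output_header(config, scheme), con)
  utils::write.table(manifest, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  log_stage(config, "run_extract: %d file(s), %d molecule(s), %d kept",
            length(files), nrow(manifest),
            sum(manifest$status == "kept"))
  invisible(manifest)
}

#' Run the full pipeline: extract, charge, fingerprint, search
#'
#' Extracts ligands ([run_extract()]), guarantees partial charges
#' (file-supplied or Gasteiger per `config$charge_mode`), fingerprints the
#' survivors, writes the fingerprint TSV and the reduced top-k
#' dissimilarity matrix. Deterministic for fixed inputs and seed.
#'
#' @param config a [run_config()].
#' @return list with `fingerprints` (matrix) and `matrix`
#'   ([reduced_matrix()]), invisibly.
#' @export
run_pipeline <- function(config) {
  manifest <- run_extract(config)
  scheme <- tier_scheme(config$boundaries)
  kept <- manifest$mol_id[manifest$status == "kept"]
  if (length(kept) == 0) stop("run_pipeline(): no molecule passed the filters")
  mols <- lapply(kept, function(id) {
    mol <- parse_structure(file.path(config$out_dir, paste0(id, ".pdb")),
                           "pdb")[[1]]
    mol$mol_id <- id
    if (config$charge_mode == "gasteiger") assign_gasteiger(mol)
    else ensure_charges(mol)
  })
  log_stage(config, "run_pipeline: %d molecule(s) charged (%s)",
            length(mols), config$charge_mode)
  fps <- fingerprint_set(mols, scheme)
  hdr <- output_header(config, scheme)
  write_fingerprints(fps, file.path(config$out_dir, "fingerprints.tsv"),
                     header_extra = hdr)
  out <- list(fingerprints = fps, matrix = NULL)
  if (nrow(fps) >= 2) {
    out$matrix <- reduced_matrix(fps, top_k = config$top_k)
    write_results(out$matrix, file.path(config$out_dir, "matrix_top.tsv"),
                  header_extra = hdr)
  }
  log_stage(config, "run_pipeline: %d fingerprint(s) written", nrow(fps))
  invisible(out)
}
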