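#' Read a coarse reference structure
#'
#' Builds the [site_model()] shared by all analysis stages from a reference
#' structure: one C-alpha site per protein residue and one backbone-P site per
#' nucleotide. Accepts a PDB file or a frame-table (the first frame supplies
#' the reference coordinates; site roles/labels come from the header).
#'
#' @param path file path
#' @param domain_ranges protein domain ranges, see [site_model()]
#' @param role_rules list with `ca_atom` and `p_atom`, the atom names that
#'   define protein and DNA sites (defaults `"CA"` and `"P"`)
#' @param format `"auto"`, `"pdb"` or `"frame-table"`
#' @return a [site_model()], protein sites first, both blocks sorted by label
#' @export
load_structure <- function(path, domain_ranges = default_domain_ranges(),
                           role_rules = list(ca_atom = "CA", p_atom = "P"),
                           format = c("auto", "pdb", "frame-table")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "frame-table"
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    at <- pdb$atom
    is_prot <- at$elety == role_rules$ca_atom
    is_dna <- at$elety == role_rules$p_atom
    keep <- is_prot | is_dna
    if (!any(keep)) stop("no ", role_rules$ca_atom, "/", role_rules$p_atom,
                         " atoms found in ", path)
    # every residue present in the file must yield exactly one site
    res_all <- unique(at[, c("chain", "resno")])
    res_hit <- unique(at[keep, c("chain", "resno")])
    miss <- !paste(res_all$chain, res_all$resno) %in% paste(res_hit$chain, res_hit$resno)
    if (any(miss))
      stop("residue(s) without a ", role_rules$ca_atom, " or ", role_rules$p_atom,
           " site: ", paste(res_all$resno[miss], collapse = ", "))
    at <- at[keep, , drop = FALSE]
    site_model(label = at$resno,
               role = ifelse(at$elety == role_rules$ca_atom, "CA", "P"),
               coords = cbind(at$x, at$y, at$z),
               domain_ranges = domain_ranges)
  } else {
    hdr <- parse_frame_table_header(readLines(path, n = 1L))
    xyz <- read_frame_table_xyz(path, n_sites = nrow(hdr))
    site_model(label = hdr$label, role = hdr$role,
               coords = matrix(xyz[1, ], ncol = 3, byrow = TRUE),
               domain_ranges = domain_ranges)
  }
}

#' Write a site model as a PDB file
#'
#' Protein sites are written as CA atoms on chain A, DNA sites as P atoms on
#' chain B, residue numbers equal to the site labels.
#' @param sm a [site_model()]
#' @param path output file
#' @export
write_structure <- function(sm, path) {
  stopifnot(inherits(sm, "site_model"))
  co <- ref_coords(sm)
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(co)),
                   resno = sm$label,
                   resid = ifelse(sm$role == "CA", "ALA", "DA"),
                   elety = sm$role,
                   chain = ifelse(sm$role == "CA", "A", "B"))
  invisible(path)
}

#' Load a conformational ensemble
#'
#' @param path trajectory file
#' @param site_model the [site_model()] the frames must match
#' @param format `"auto"`, `"frame-table"`, `"pdb"` (multi-model) or `"dcd"`.
#'   XTC is not supported; convert to DCD or frame-table first.
#' @param times optional per-frame times (ps)
#' @return an [ensemble()], `aligned = FALSE`, frames in file order
#' @export
load_ensemble <- function(path, site_model,
                          format = c("auto", "frame-table", "pdb", "dcd", "xtc"),
                          times = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", dcd = "dcd", xtc = "xtc", "frame-table")
  }
  n <- nrow(site_model)
  xyz <- switch(format,
    "frame-table" = {
      hdr <- parse_frame_table_header(readLines(path, n = 1L))
      if (nrow(hdr) != n)
        stop("frame-table has ", nrow(hdr), " sites; site model has ", n)
      read_frame_table_xyz(path, n_sites = n)
    },
    "pdb" = {
      pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
      xyz <- pdb$xyz
      if (ncol(xyz) != 3L * n)
        stop("multi-model PDB has ", ncol(xyz) / 3, " sites; site model has ", n)
      unclass(xyz)
    },
    "dcd" = {
      xyz <- bio3d::read.dcd(path, verbose = FALSE)
      if (ncol(xyz) != 3L * n)
        stop("DCD has ", ncol(xyz) / 3, " sites; site model has ", n)
      unclass(xyz)
    },
    "xtc" = stop("XTC reading is not supported; supply DCD, multi-model PDB ",
                 "or frame-table input")
  )
  ensemble(xyz_to_frames(xyz), site_model, times = times, aligned = FALSE)
}

#' Write an ensemble as a frame-table
#'
#' The frame-table is a plain-text interchange format: one tab-separated
#' header line of `role:label` site tokens, then one line per frame holding
#' `3N` floats (`x1 y1 z1 x2 ...`, Angstrom) printed with enough digits to
#' round-trip bit-identically.
#' @param e an [ensemble()]
#' @param path output file
#' @export
write_frame_table <- function(e, path) {
  stopifnot(inherits(e, "ensemble"))
  sm <- e$site_model
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(sprintf("%s:%d", sm$role, sm$label), collapse = "\t"), con)
  xyz <- ensemble_xyz(e)
  for (i in seq_len(nrow(xyz)))
    writeLines(paste(sprintf("%.17g", xyz[i, ]), collapse = "\t"), con)
  invisible(path)
}

parse_frame_table_header <- function(line) {
  tok <- strsplit(trimws(line), "\t", fixed = TRUE)[[1]]
  m <- regmatches(tok, regexec("^(CA|P):(-?[0-9]+)$", tok))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("malformed frame-table header token(s): ",
                     paste(tok[bad], collapse = ", "))
  data.frame(role = vapply(m, `[`, "", 2L),
             label = as.integer(vapply(m, `[`, "", 3L)),
             stringsAsFactors = FALSE)
}

read_frame_table_xyz <- function(path, n_sites) {
  lines <- readLines(path)[-1L]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("frame-table contains no frames")
  rows <- lapply(seq_along(lines), function(i) {
    v <- as.numeric(strsplit(lines[[i]], "\t", fixed = TRUE)[[1]])
    if (length(v) != 3L * n_sites || anyNA(v))
      stop("frame ", i, " is truncated or malformed (expected ",
           3L * n_sites, " values)")
    v
  })
  do.call(rbind, rows)
}

#' Write / read a labelled numeric matrix as TSV
#'
#' Row and column headers are site labels (or any dimnames present); values
#' are printed with full precision so write-then-read round-trips exactly.
#' `NA` entries (e.g. masked free-energy bins) are written as the literal
#' `NA` sentinel.
#' @param m numeric matrix
#' @param path file path
#' @export
write_matrix <- function(m, path) {
  m <- as.matrix(m)
  if (!is.numeric(m)) stop("write_matrix expects a numeric matrix")
  if (is.null(rownames(m))) rownames(m) <- seq_len(nrow(m))
  if (is.null(colnames(m))) colnames(m) <- seq_len(ncol(m))
  txt <- matrix(ifelse(is.na(m), "NA", sprintf("%.17g", m)), nrow = nrow(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[i], txt[i, ]), collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  as.matrix(d)
}

#' Write / read a records table as TSV
#' @param records a data frame
#' @param path file path
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  utils::write.table(format_full_precision(records), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

format_full_precision <- function(df) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  df
}

#' Read / write a flat key=value configuration file
#'
#' Values are parsed as logical (`true`/`false`), numeric when possible, and
#' comma-separated lists become vectors. Round-trips through
#' [write_config()].
#' @param path file path
#' @return named list
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("malformed config line: '", ln, "'")
    key <- trimws(substr(ln, 1L, eq - 1L))
    val <- trimws(substr(ln, eq + 1L, nchar(ln)))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    parsed <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(parsed)) parsed
      else if (all(tolower(parts) %in% c("true", "false"))) tolower(parts) == "true"
      else parts
  }
  out
}

#' @rdname read_config
#' @param config named list
#' @export
write_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  fmt <- vapply(config, function(v) {
    if (is.double(v)) paste(sprintf("%.17g", v), collapse = ",")
    else if (is.logical(v)) paste(ifelse(v, "true", "false"), collapse = ",")
    else paste(v, collapse = ",")
  }, "")
  writeLines(paste0(names(config), " = ", fmt), path)
  invisible(path)
}
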