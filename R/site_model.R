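#' Coarse site model of a protein--DNA complex
#'
#' A `site_model` is the shared reference frame of every analysis stage: one
#' site per protein residue (its C-alpha) and one per nucleotide (its backbone
#' phosphate), each carrying a residue/nucleotide label, a role, a structural
#' domain and reference coordinates. Protein sites precede DNA sites and both
#' blocks are ordered by label, so row `i` of any matrix produced downstream
#' always refers to the same site.
#'
#' @param label integer residue/nucleotide numbers (1-based, as in the source
#'   structure). Must be unique within each role.
#' @param role character, `"CA"` (protein C-alpha) or `"P"` (DNA phosphate).
#' @param coords numeric `n x 3` matrix of reference coordinates in Angstrom.
#' @param domain_ranges named list of `c(first, last)` label ranges assigning
#'   protein residues to domains, e.g. the polymerase-beta architecture
#'   `list(LYASE = c(10, 87), D = c(90, 150), C = c(151, 260), N = c(261, 335))`.
#'   Protein residues outside every range are classed `"LINKER"`; `"P"` sites
#'   are always `"DNA"`.
#' @param mass per-site masses (amu); default equal (1).
#'
#' @return An object of class `site_model`: a data frame with columns
#'   `label`, `role`, `domain`, `x`, `y`, `z`, `mass`, one row per site,
#'   protein sites first.
#' @export
site_model <- function(label, role, coords, domain_ranges = default_domain_ranges(),
                       mass = NULL) {
  label <- as.integer(label)
  role <- as.character(role)
  stopifnot(length(label) == length(role))
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L || nrow(coords) != length(label))
    stop("coords must be an n x 3 matrix matching the number of sites")
  if (!all(is.finite(coords)))
    stop("reference coordinates must be finite")
  if (!all(role %in% c("CA", "P")))
    stop("role must be 'CA' or 'P'")
  for (r in c("CA", "P")) {
    dup <- duplicated(label[role == r])
    if (any(dup))
      stop("duplicate site label(s) within role ", r, ": ",
           paste(unique(label[role == r][dup]), collapse = ", "))
  }
  validate_domain_ranges(domain_ranges)
  if (is.null(mass)) mass <- rep(1, length(label))
  stopifnot(length(mass) == length(label), all(mass > 0))

  domain <- ifelse(role == "P", "DNA", NA_character_)
  for (dn in names(domain_ranges)) {
    rg <- domain_ranges[[dn]]
    hit <- role == "CA" & label >= rg[1] & label <= rg[2]
    domain[hit] <- dn
  }
  domain[is.na(domain)] <- "LINKER"

  sm <- data.frame(label = label, role = role, domain = domain,
                   x = coords[, 1], y = coords[, 2], z = coords[, 3],
                   mass = mass, stringsAsFactors = FALSE)
  ord <- order(sm$role != "CA", sm$label)  # protein block first, then DNA
  sm <- sm[ord, , drop = FALSE]
  rownames(sm) <- NULL
  class(sm) <- c("site_model", "data.frame")
  sm
}

#' @export
print.site_model <- function(x, ...) {
  cat("site_model:", nrow(x), "sites (",
      sum(x$role == "CA"), "CA,", sum(x$role == "P"), "P )\n")
  cat("domains:", paste(sprintf("%s=%d", names(table(x$domain)), table(x$domain)),
                        collapse = " "), "\n")
  invisible(x)
}

default_domain_ranges <- function() {
  list(LYASE = c(10, 87), D = c(90, 150), C = c(151, 260), N = c(261, 335))
}

validate_domain_ranges <- function(domain_ranges) {
  if (!length(domain_ranges)) return(invisible(TRUE))
  if (is.null(names(domain_ranges)) || any(names(domain_ranges) == ""))
    stop("domain_ranges must be a named list")
  rg <- lapply(domain_ranges, function(r) {
    if (length(r) != 2L || r[1] > r[2]) stop("each domain range is c(first, last)")
    r
  })
  # ranges must be pairwise disjoint
  m <- do.call(rbind, rg)
  o <- order(m[, 1])
  m <- m[o, , drop = FALSE]
  if (nrow(m) > 1L && any(m[-1, 1] <= m[-nrow(m), 2]))
    stop("domain ranges overlap")
  invisible(TRUE)
}

#' Reference coordinates of a site model as a matrix
#' @param sm a `site_model`
#' @return numeric `n x 3` matrix (Angstrom)
#' @export
ref_coords <- function(sm) {
  stopifnot(inherits(sm, "site_model"))
  as.matrix(sm[, c("x", "y", "z")])
}

#' Resolve a site selection to row indices
#'
#' Selections name sites by domain (`"LYASE"`, `"D"`, `"C"`, `"N"`, `"DNA"`,
#' `"LINKER"`), role (`"CA"`, `"P"`), the keyword `"all"`, label ranges
#' (`"44"`, `"10-87"`), or any union of these as a character vector. Label
#' selectors apply to protein (CA) sites unless prefixed `"P:"`.
#'
#' @param sm a `site_model`
#' @param expr character vector of selectors, or an integer vector of row
#'   indices passed through unchanged.
#' @return sorted, duplicate-free integer row indices into `sm`
#' @export
select_sites <- function(sm, expr = "all") {
  stopifnot(inherits(sm, "site_model"))
  if (is.numeric(expr)) {
    idx <- as.integer(expr)
    if (any(idx < 1L | idx > nrow(sm))) stop("site index out of range")
    return(sort(unique(idx)))
  }
  idx <- integer(0)
  for (tok in expr) {
    tok <- trimws(tok)
    if (tok == "all") {
      idx <- c(idx, seq_len(nrow(sm)))
    } else if (tok %in% c("CA", "P")) {
      idx <- c(idx, which(sm$role == tok))
    } else if (tok %in% unique(sm$domain)) {
      idx <- c(idx, which(sm$domain == tok))
    } else {
      role <- "CA"
      if (startsWith(tok, "P:")) { role <- "P"; tok <- sub("^P:", "", tok) }
      if (grepl("^[0-9]+-[0-9]+$", tok)) {
        ab <- as.integer(strsplit(tok, "-", fixed = TRUE)[[1]])
        hit <- which(sm$role == role & sm$label >= ab[1] & sm$label <= ab[2])
      } else if (grepl("^[0-9]+$", tok)) {
        hit <- which(sm$role == role & sm$label == as.integer(tok))
      } else {
        stop("unrecognised selector: '", tok, "'")
      }
      if (!length(hit)) stop("selector '", tok, "' matches no site")
      idx <- c(idx, hit)
    }
  }
  idx <- sort(unique(idx))
  if (!length(idx)) stop("selection resolved to zero sites")
  idx
}

#' Row index of a single labelled site
#' @param sm a `site_model`
#' @param label residue/nucleotide number
#' @param role `"CA"` or `"P"`
#' @return integer row index
#' @export
site_index <- function(sm, label, role = "CA") {
  i <- which(sm$label == label & sm$role == role)
  if (length(i) != 1L)
    stop("site with label ", label, " and role ", role, " not found")
  i
}
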