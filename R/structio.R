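# Structure / trajectory data model, PDB and DCD readers, atom selection.

#' Construct a structure model
#'
#' A structure model bundles an atom table (names, residues, chains and
#' optional force-field parameters) with one set of Cartesian coordinates in
#' Angstrom. Atom order is stable: every derived quantity (selections,
#' matrices, energy tables) refers to atoms in this order.
#'
#' @param atoms data.frame with columns `atom`, `element`, `resname`,
#'   `resno` (author numbering), `chain`, and optionally `charge`, `radius`,
#'   `eps`, `rmin_half`.
#' @param xyz numeric N x 3 matrix of coordinates (Angstrom).
#' @return An object of class `md_structure`.
#' @export
md_structure <- function(atoms, xyz) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("atom", "element", "resname", "resno", "chain")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table is missing column(s): ", paste(miss, collapse = ", "))
  xyz <- as.matrix(xyz)
  if (nrow(atoms) == 0L) stop("empty model: no atoms")
  if (!is.numeric(xyz) || ncol(xyz) != 3L || nrow(xyz) != nrow(atoms))
    stop("xyz must be a numeric matrix with 3 columns and one row per atom")
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  if ("radius" %in% names(atoms)) {
    r <- atoms$radius
    if (any(!is.na(r) & r <= 0)) stop("intrinsic radius must be > 0")
  }
  key <- paste(atoms$chain, atoms$resno, atoms$atom)
  if (anyDuplicated(key))
    stop("duplicate (chain, resno, atom) triple: ", key[anyDuplicated(key)])
  for (col in c("charge", "radius", "eps", "rmin_half"))
    if (!col %in% names(atoms)) atoms[[col]] <- NA_real_
  rownames(atoms) <- NULL
  dimnames(xyz) <- NULL
  structure(list(atoms = atoms, xyz = xyz), class = "md_structure")
}

#' @export
print.md_structure <- function(x, ...) {
  ch <- chain_table(x)
  cat("md_structure:", nrow(x$atoms), "atoms,",
      length(unique(residue_ids(x))), "residues,",
      nrow(ch), "chain(s)\n")
  for (i in seq_len(nrow(ch)))
    cat("  chain ", ch$chain[i], ": ", ch$n_atoms[i], " atoms\n", sep = "")
  invisible(x)
}

#' Chain partition of a structure
#'
#' @param model an `md_structure`.
#' @return data.frame with one row per chain: `chain`, `first`, `last`
#'   (atom index range), `n_atoms`.
#' @export
chain_table <- function(model) {
  ch <- model$atoms$chain
  u <- unique(ch)
  data.frame(chain = u,
             first = match(u, ch),
             last = length(ch) - match(u, rev(ch)) + 1L,
             n_atoms = as.integer(table(factor(ch, levels = u))),
             stringsAsFactors = FALSE)
}

# "chain:resno" id per atom; residue identity everywhere in the package
residue_ids <- function(model, idx = NULL) {
  a <- model$atoms
  if (!is.null(idx)) a <- a[idx, , drop = FALSE]
  paste0(a$chain, ":", a$resno)
}

# "chain:resno:resname" display label (e.g. "M:82:GLU")
residue_labels <- function(model, idx = NULL) {
  a <- model$atoms
  if (!is.null(idx)) a <- a[idx, , drop = FALSE]
  paste0(a$chain, ":", a$resno, ":", a$resname)
}

#' Construct a trajectory ensemble
#'
#' @param topology an `md_structure` giving atom identities.
#' @param coords numeric array of dimension F x N x 3 (frames, atoms, xyz),
#'   in Angstrom.
#' @param frame_times optional numeric vector of frame times (ns).
#' @param start first frame used by analyses (equilibration discard);
#'   defaults to 1, i.e. no discard.
#' @return An object of class `md_trajectory`.
#' @export
md_trajectory <- function(topology, coords, frame_times = NULL, start = 1L) {
  if (!inherits(topology, "md_structure")) stop("topology must be an md_structure")
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("coords must be an F x N x 3 array")
  if (dim(coords)[2] != nrow(topology$atoms))
    stop("atom count mismatch: topology has ", nrow(topology$atoms),
         " atoms, frames have ", dim(coords)[2])
  nf <- dim(coords)[1]
  if (nf < 1L) stop("trajectory must have at least one frame")
  start <- as.integer(start)
  if (start < 1L || start > nf)
    stop("analysis start frame ", start, " outside 1..", nf)
  if (!is.null(frame_times) && length(frame_times) != nf)
    stop("frame_times length must equal the frame count")
  structure(list(topology = topology, coords = coords,
                 frame_times = frame_times, start = start),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("md_trajectory:", dim(x$coords)[1], "frames x",
      dim(x$coords)[2], "atoms; analysis frames ",
      x$start, "..", dim(x$coords)[1], "\n", sep = " ")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `md_trajectory`.
#' @param analysis if `TRUE`, count only post-equilibration frames.
#' @return integer frame count.
#' @export
n_frames <- function(traj, analysis = FALSE) {
  nf <- dim(traj$coords)[1]
  if (analysis) nf - traj$start + 1L else nf
}

# frame indices entering analyses
analysis_frames <- function(traj) seq.int(traj$start, dim(traj$coords)[1])

# single frame as an N x 3 matrix
frame_xyz <- function(traj, i) {
  m <- traj$coords[i, , , drop = TRUE]
  dim(m) <- c(dim(traj$coords)[2], 3L)
  m
}

# ---- PDB reading -----------------------------------------------------------

# pre-scan for malformed ATOM/HETATM records so errors carry line numbers
validate_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed ATOM record at line ", i, ": record shorter than 54 columns")
    for (cols in list(c(31, 38), c(39, 46), c(47, 54))) {
      f <- substr(ln, cols[1], cols[2])
      if (is.na(suppressWarnings(as.numeric(f))))
        stop("malformed ATOM record at line ", i,
             ": non-numeric coordinate field '", trimws(f), "'")
    }
  }
  invisible(sum(is_atom))
}

# altloc resolution: keep the highest-occupancy conformer per
# (chain, resno, atom); ties broken by altloc letter (A first)
resolve_altloc <- function(atom) {
  alt <- atom$alt
  alt[is.na(alt)] <- ""
  if (all(alt == "")) return(seq_len(nrow(atom)))
  key <- paste(atom$chain, atom$resno, atom$insert, atom$elety)
  occ <- atom$o
  occ[is.na(occ)] <- 1
  keep <- rep(TRUE, nrow(atom))
  for (k in unique(key[alt != ""])) {
    idx <- which(key == k)
    if (length(idx) < 2L) next
    ord <- order(-occ[idx], alt[idx])
    keep[idx[-ord[1]]] <- FALSE
  }
  which(keep)
}

bio3d_atoms_to_df <- function(atom) {
  el <- trimws(as.character(atom$elesy))
  guess <- toupper(substr(trimws(atom$elety), 1, 1))
  el[is.na(el) | el == ""] <- guess[is.na(el) | el == ""]
  data.frame(atom = trimws(atom$elety),
             element = toupper(el),
             resname = trimws(atom$resid),
             resno = as.integer(atom$resno),
             chain = ifelse(is.na(atom$chain) | atom$chain == "", "A",
                            as.character(atom$chain)),
             stringsAsFactors = FALSE)
}

#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records of the first model, preserving atom order,
#' author residue numbering and chain identifiers. Alternate locations are
#' resolved to the highest-occupancy conformer. Malformed coordinate fields
#' raise an error naming the offending line.
#'
#' @param path path to a PDB file.
#' @param format input format; only `"pdb"`.
#' @return An `md_structure`.
#' @export
read_structure <- function(path, format = "pdb") {
  format <- match.arg(format, "pdb")
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  n_atom_lines <- validate_pdb_lines(lines)
  if (n_atom_lines == 0L) stop("empty model: no ATOM/HETATM records in ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE)
  keep <- resolve_altloc(pdb$atom)
  atom <- pdb$atom[keep, , drop = FALSE]
  xyz <- cbind(atom$x, atom$y, atom$z)
  md_structure(bio3d_atoms_to_df(atom), xyz)
}

#' Write a structure (or coordinate frames) to a PDB file
#'
#' @param model an `md_structure`.
#' @param path output path.
#' @param xyz optional F x N x 3 array (or N x 3 matrix) of coordinates to
#'   write instead of the model's own; several frames produce a multi-model
#'   PDB (MODEL/ENDMDL).
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, xyz = NULL) {
  a <- model$atoms
  if (is.null(xyz)) xyz <- model$xyz
  if (is.matrix(xyz)) {
    flat <- matrix(t(xyz), nrow = 1)
  } else {
    stopifnot(length(dim(xyz)) == 3L)
    flat <- t(apply(xyz, 1, function(m) as.vector(t(m))))
  }
  bio3d::write.pdb(file = path, xyz = flat, elety = a$atom,
                   resid = a$resname, resno = a$resno, chain = a$chain)
  invisible(path)
}

# ---- trajectory reading ----------------------------------------------------

#' Read a coordinate trajectory
#'
#' Supported formats: multi-model PDB and (CHARMM/X-PLOR) DCD, both carrying
#' coordinates in Angstrom. The frame atom count must match the topology.
#'
#' @param path trajectory file.
#' @param topology `md_structure` describing each frame's atoms.
#' @param format `"pdb"`, `"dcd"`, or `NULL` to infer from the extension.
#' @param start first analysis frame (equilibration discard), default 1.
#' @return An `md_trajectory`.
#' @export
read_trajectory <- function(path, topology, format = NULL, start = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("pdb", "ent")) "pdb" else ext
  }
  na <- nrow(topology$atoms)
  if (format == "pdb") {
    lines <- readLines(path, warn = FALSE)
    validate_pdb_lines(lines)
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    flat <- pdb$xyz
    if (!is.matrix(flat)) flat <- matrix(flat, nrow = 1)
    found <- ncol(flat) / 3L
    if (found != na)
      stop("atom count mismatch: topology expects ", na, ", trajectory has ", found)
    nf <- nrow(flat)
  } else if (format == "dcd") {
    flat <- bio3d::read.dcd(path, verbose = FALSE)
    if (!is.matrix(flat)) flat <- matrix(flat, nrow = 1)
    found <- ncol(flat) / 3L
    if (found != na)
      stop("atom count mismatch: topology expects ", na, ", trajectory has ", found)
    nf <- nrow(flat)
  } else if (format == "xtc") {
    stop("unsupported trajectory format 'xtc': convert to DCD or multi-model ",
         "PDB (supported formats: pdb, dcd)")
  } else {
    stop("unsupported trajectory format '", format, "' (supported: pdb, dcd)")
  }
  coords <- array(NA_real_, dim = c(nf, na, 3L))
  for (f in seq_len(nf))
    coords[f, , ] <- matrix(flat[f, ], ncol = 3L, byrow = TRUE)
  md_trajectory(topology, coords, start = start)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj an `md_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  write_structure(traj$topology, path, xyz = traj$coords)
}

#' Write a trajectory as a CHARMM-format DCD file
#'
#' Minimal single-precision DCD writer (no unit cell), used mainly by the
#' synthetic generator; frames are written in Angstrom.
#'
#' @param traj an `md_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- dim(traj$coords)[1]; na <- dim(traj$coords)[2]
  wrec <- function(writer) {
    raw_con <- rawConnection(raw(0), "wb")
    writer(raw_con)
    payload <- rawConnectionValue(raw_con)
    close(raw_con)
    writeBin(length(payload), con, size = 4L)
    writeBin(payload, con)
    writeBin(length(payload), con, size = 4L)
  }
  wrec(function(c2) {
    writeChar("CORD", c2, nchars = 4, eos = NULL)
    icntrl <- integer(20)
    icntrl[1] <- nf          # number of frames
    icntrl[2] <- 1L          # first step
    icntrl[3] <- 1L          # save interval
    icntrl[4] <- nf          # total steps
    icntrl[20] <- 24L        # CHARMM version flag
    writeBin(icntrl[1:9], c2, size = 4L)
    writeBin(1.0, c2, size = 4L)       # DELTA as float (CHARMM convention)
    writeBin(icntrl[11:20], c2, size = 4L)
  })
  wrec(function(c2) {
    writeBin(1L, c2, size = 4L)
    title <- sprintf("%-80s", "created by mdpost")
    writeChar(title, c2, nchars = 80, eos = NULL)
  })
  wrec(function(c2) writeBin(na, c2, size = 4L))
  for (f in seq_len(nf)) {
    m <- frame_xyz(traj, f)
    for (ax in 1:3) wrec(function(c2) writeBin(m[, ax], c2, size = 4L))
  }
  invisible(path)
}

# ---- force-field parameter table -------------------------------------------

#' Read a force-field parameter table and attach it to a structure
#'
#' Whitespace-delimited text with header
#' `chain resnum atom charge radius eps rmin_half`; units are elementary
#' charges, Angstrom, kcal/mol and Angstrom. Rows are matched to atoms by
#' (chain, residue number, atom name).
#'
#' @param path parameter file.
#' @param model `md_structure` to decorate.
#' @return The model with `charge`, `radius`, `eps`, `rmin_half` filled in.
#' @export
read_ff_params <- function(path, model) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("chain", "resnum", "atom", "charge", "radius", "eps", "rmin_half")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("parameter table is missing column(s): ", paste(miss, collapse = ", "))
  if (any(tab$radius <= 0)) stop("intrinsic radius must be > 0")
  key_m <- paste(model$atoms$chain, model$atoms$resno, model$atoms$atom)
  key_t <- paste(tab$chain, tab$resnum, tab$atom)
  hit <- match(key_m, key_t)
  unmatched <- key_t[!key_t %in% key_m]
  if (length(unmatched))
    warning("parameter rows matching no atom: ",
            paste(utils::head(unmatched, 5), collapse = "; "))
  model$atoms$charge <- tab$charge[hit]
  model$atoms$radius <- tab$radius[hit]
  model$atoms$eps <- tab$eps[hit]
  model$atoms$rmin_half <- tab$rmin_half[hit]
  model
}

#' Write the force-field parameter table of a structure
#'
#' @param model `md_structure` whose atoms carry parameters.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ff_params <- function(model, path) {
  a <- model$atoms
  tab <- data.frame(chain = a$chain, resnum = a$resno, atom = a$atom,
                    charge = a$charge, radius = a$radius, eps = a$eps,
                    rmin_half = a$rmin_half)
  utils::write.table(tab, path, quote = FALSE, row.names = FALSE, sep = " ")
  invisible(path)
}

# ---- atom selection --------------------------------------------------------

# Tokenizer + recursive-descent parser for a small selection grammar:
#   expr    := or
#   or      := and ("or" and)*
#   and     := unary ("and" unary)*
#   unary   := "not" unary | "(" expr ")" | predicate
#   pred    := "all" | "heavy" | "ca" |
#              ("name"|"resname"|"chain") value+ |
#              "resid" range+          (range = 12 or 5-9)
sel_tokenize <- function(expr) {
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, expr)[[1]]
  if (m[1] == -1) stop("selection syntax error at position 1: empty expression")
  data.frame(tok = regmatches(expr, gregexpr(pat, expr))[[1]],
             pos = as.integer(m), stringsAsFactors = FALSE)
}

#' Select atoms of a structure
#'
#' Evaluates a small selection expression over atom name, residue name,
#' residue number ranges, chain id, and the keywords `all`, `heavy`
#' (non-hydrogen) and `ca` (alpha carbons). Terms combine with `and`, `or`,
#' `not` and parentheses, e.g. `"chain B and heavy"` or
#' `"resid 27-28 and chain M"`.
#'
#' @param model an `md_structure`.
#' @param expr selection expression (character).
#' @return Integer vector of atom indices in topology order (possibly empty).
#' @export
select_atoms <- function(model, expr) {
  stopifnot(is.character(expr), length(expr) == 1L)
  toks <- sel_tokenize(expr)
  a <- model$atoms
  i <- 0L
  n <- nrow(toks)
  peek <- function() if (i < n) toks$tok[i + 1L] else NA_character_
  advance <- function() { i <<- i + 1L; toks$tok[i] }
  err <- function(msg, at = i + 1L) {
    pos <- if (at <= n) toks$pos[at] else nchar(expr) + 1L
    stop("selection syntax error at position ", pos, ": ", msg)
  }
  keywords <- c("and", "or", "not", "(", ")", "all", "heavy", "ca",
                "name", "resname", "chain", "resid")
  parse_values <- function() {
    vals <- character(0)
    while (!is.na(peek()) && !(peek() %in% keywords)) vals <- c(vals, advance())
    if (!length(vals)) err("keyword requires at least one value")
    vals
  }
  parse_pred <- function() {
    tok <- peek()
    if (is.na(tok)) err("unexpected end of expression")
    if (tok == "(") {
      advance()
      v <- parse_or()
      if (!identical(peek(), ")")) err("expected ')'")
      advance()
      return(v)
    }
    advance()
    switch(tok,
      all = rep(TRUE, nrow(a)),
      heavy = a$element != "H",
      ca = a$atom == "CA",
      name = a$atom %in% parse_values(),
      resname = a$resname %in% parse_values(),
      chain = a$chain %in% parse_values(),
      resid = {
        vals <- parse_values()
        keep <- rep(FALSE, nrow(a))
        for (v in vals) {
          if (grepl("^-?[0-9]+--?[0-9]+$", v) || grepl("^[0-9]+-[0-9]+$", v)) {
            parts <- as.integer(strsplit(sub("^(-?[0-9]+)-", "\\1 ", v), " ")[[1]])
            keep <- keep | (a$resno >= parts[1] & a$resno <= parts[2])
          } else if (grepl("^-?[0-9]+$", v)) {
            keep <- keep | a$resno == as.integer(v)
          } else err(paste0("bad residue range '", v, "'"), at = i)
        }
        keep
      },
      err(paste0("unknown keyword '", tok, "'"), at = i)
    )
  }
  parse_unary <- function() {
    if (identical(peek(), "not")) { advance(); return(!parse_unary()) }
    parse_pred()
  }
  parse_and <- function() {
    v <- parse_unary()
    while (identical(peek(), "and")) { advance(); v <- v & parse_unary() }
    v
  }
  parse_or <- function() {
    v <- parse_and()
    while (identical(peek(), "or")) { advance(); v <- v | parse_and() }
    v
  }
  mask <- parse_or()
  if (i != n) err("trailing tokens")
  which(mask)
}
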