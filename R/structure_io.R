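# Multi-model structure input/output.  PDB parsing is delegated to bio3d;
# mmCIF (needed for >62-monomer assemblies) is handled by a minimal
# atom_site-loop reader/writer.

PDB_CHAIN_POOL <- c(LETTERS, letters, as.character(0:9))

#' Read a multi-model structure file into a trajectory
#'
#' One trajectory frame is created per model; monomer identity is taken from
#' the chain identifier (PDB) or `auth_asym_id` (mmCIF).  Particles named
#' like coarse-grained beads (`BB`, `SC1`..`SC4`, `LP`) mark the model as
#' coarse-grained; masses are filled from element or residue tables.
#'
#' @param path file path.
#' @param format `"mmcif"`, `"pdb"` or `"auto"` (extension/content sniffing).
#' @param cg_bead_names bead names that flag a coarse-grained model.
#' @return an [oligo_trajectory()].
#' @export
read_structure <- function(path, format = c("auto", "mmcif", "pdb"),
                           cg_bead_names = c(CG_BEAD_NAMES, "LP")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif"
    else if (ext %in% c("pdb", "ent")) "pdb"
    else {
      head1 <- readLines(path, n = 5L, warn = FALSE)
      if (any(grepl("^data_|^_atom_site", head1))) "mmcif" else "pdb"
    }
  }
  models <- if (format == "mmcif") read_mmcif_models(path) else read_pdb_models(path)
  frames <- vector("list", length(models))
  ref_ids <- sort(unique(models[[1L]]$monomer_id))
  for (m in seq_along(models)) {
    at <- models[[m]]
    ids <- sort(unique(at$monomer_id))
    if (!identical(ids, ref_ids))
      stop("inconsistent monomer sets across models (model ", m, "): ",
           paste(symdiff_chr(ids, ref_ids), collapse = ", "), call. = FALSE)
    res <- if (all(at$atom_name %in% cg_bead_names)) "coarse_grained" else "full_atom"
    at <- fill_masses(at, res)
    frames[[m]] <- oligomer_frame(at, frame_index = m - 1L, resolution = res)
  }
  oligo_trajectory(frames, metadata = list(source = path, format = format))
}

symdiff_chr <- function(a, b) union(setdiff(a, b), setdiff(b, a))

read_pdb_models <- function(path) {
  # Validate model blocks up front: bio3d silently mangles files whose
  # models carry different atom sets.
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (length(starts) > 1L) {
    ends <- grep("^ENDMDL", lines)
    sig <- lapply(seq_along(starts), function(m) {
      blk <- lines[starts[m]:ends[m]]
      at <- blk[grepl("^(ATOM|HETATM)", blk)]
      list(n = length(at), chains = sort(unique(substr(at, 22L, 22L))))
    })
    for (m in seq_along(sig)[-1L]) {
      if (!identical(sig[[m]], sig[[1L]]))
        stop("inconsistent monomer sets across models (model ", m,
             " differs from model 1)", call. = FALSE)
    }
  }
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e)
                    stop("PDB parse error in '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  n <- nrow(a)
  lapply(seq_len(nrow(xyz)), function(m) {
    xi <- matrix(xyz[m, ], ncol = 3L, byrow = TRUE)
    atom_table(serial = a$eleno, atom_name = a$elety, residue_name = a$resid,
               residue_number = a$resno, monomer_id = a$chain,
               x = xi[, 1L], y = xi[, 2L], z = xi[, 3L],
               element = if ("elesy" %in% names(a)) a$elesy else NA_character_)
  })
}

read_mmcif_models <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grep("^_atom_site\\.", lines)
  if (!length(hdr_idx))
    stop("mmCIF parse error in '", path, "': no _atom_site loop found",
         call. = FALSE)
  fields <- sub("^_atom_site\\.", "", trimws(lines[hdr_idx]))
  first_row <- max(hdr_idx) + 1L
  rows <- character()
  for (i in first_row:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || grepl("^(#|loop_|data_|_)", ln)) break
    rows <- c(rows, ln)
  }
  if (!length(rows))
    stop("mmCIF parse error in '", path, "': empty atom_site loop (line ",
         first_row, ")", call. = FALSE)
  toks <- strsplit(rows, "[[:space:]]+")
  nf <- lengths(toks)
  if (any(nf != length(fields)))
    stop("mmCIF parse error in '", path, "': line ",
         first_row + which(nf != length(fields))[1L] - 1L,
         " has ", nf[nf != length(fields)][1L], " tokens, expected ",
         length(fields), call. = FALSE)
  tab <- do.call(rbind, toks)
  colnames(tab) <- fields
  get <- function(nm, alt = NULL) {
    if (nm %in% fields) return(unquote_cif(tab[, nm]))
    if (!is.null(alt) && alt %in% fields) return(unquote_cif(tab[, alt]))
    stop("mmCIF parse error in '", path, "': missing _atom_site.", nm,
         call. = FALSE)
  }
  model <- if ("pdbx_PDB_model_num" %in% fields)
    as.integer(tab[, "pdbx_PDB_model_num"]) else rep(1L, nrow(tab))
  at <- atom_table(
    serial = as.integer(get("id")),
    atom_name = get("label_atom_id", "auth_atom_id"),
    residue_name = get("label_comp_id", "auth_comp_id"),
    residue_number = as.integer(get("auth_seq_id", "label_seq_id")),
    monomer_id = get("auth_asym_id", "label_asym_id"),
    x = as.numeric(get("Cartn_x")), y = as.numeric(get("Cartn_y")),
    z = as.numeric(get("Cartn_z")),
    element = if ("type_symbol" %in% fields) unquote_cif(tab[, "type_symbol"])
              else NA_character_)
  split_ord <- split(seq_len(nrow(at)), model)
  lapply(split_ord, function(ix) at[ix, , drop = FALSE])
}

unquote_cif <- function(x) gsub("^['\"]|['\"]$", "", x)

#' Write a trajectory as a multi-model PDB or mmCIF file
#'
#' Assemblies with more than 62 monomers cannot be indexed by single-character
#' PDB chain identifiers and must be written as mmCIF.
#'
#' @param trajectory an [oligo_trajectory()] (or single `oligomer_frame`).
#' @param path output file path.
#' @param format `"mmcif"` or `"pdb"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(trajectory, path, format = c("mmcif", "pdb")) {
  format <- match.arg(format)
  if (inherits(trajectory, "oligomer_frame"))
    trajectory <- oligo_trajectory(list(trajectory))
  ids <- monomer_ids(trajectory)
  if (format == "pdb" && length(ids) > 62L)
    stop("pdb format supports at most 62 monomers (got ", length(ids),
         "); write mmcif instead", call. = FALSE)
  lines <- if (format == "pdb") format_pdb(trajectory, ids) else
    format_mmcif(trajectory)
  writeLines(lines, path)
  invisible(path)
}

format_pdb <- function(trajectory, ids) {
  # Keep single-character alphanumeric ids; otherwise map in order.
  chain_map <- if (all(nchar(ids) == 1L & ids %in% PDB_CHAIN_POOL))
    stats::setNames(ids, ids) else stats::setNames(PDB_CHAIN_POOL[seq_along(ids)], ids)
  out <- character()
  multi <- length(trajectory$frames) > 1L
  for (f in trajectory$frames) {
    a <- f$atoms
    el <- ifelse(is.na(a$element) | !nzchar(a$element),
                 substr(a$atom_name, 1L, 1L), a$element)
    nm <- ifelse(nchar(a$atom_name) < 4L, paste0(" ", a$atom_name), a$atom_name)
    rec <- sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   a$serial %% 100000L, nm, a$residue_name,
                   chain_map[a$monomer_id], a$residue_number,
                   a$x, a$y, a$z, 1, 0, el)
    if (multi) out <- c(out, sprintf("MODEL     %4d", f$frame_index + 1L),
                        rec, "ENDMDL")
    else out <- c(out, rec)
  }
  c(out, "END")
}

format_mmcif <- function(trajectory) {
  hdr <- c("data_dynhelix", "#", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_comp_id", "label_asym_id", "label_seq_id",
                    "auth_asym_id", "auth_seq_id", "Cartn_x", "Cartn_y",
                    "Cartn_z", "occupancy", "B_iso_or_equiv",
                    "pdbx_PDB_model_num")))
  body <- unlist(lapply(trajectory$frames, function(f) {
    a <- f$atoms
    el <- ifelse(is.na(a$element) | !nzchar(a$element),
                 substr(a$atom_name, 1L, 1L), a$element)
    sprintf("ATOM %d %s %s %s %s %d %s %d %.3f %.3f %.3f 1.00 0.00 %d",
            a$serial, el, a$atom_name, a$residue_name, a$monomer_id,
            a$residue_number, a$monomer_id, a$residue_number,
            a$x, a$y, a$z, f$frame_index + 1L)
  }))
  c(hdr, body, "#")
}
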