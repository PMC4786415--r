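# Structure input/output: PDB and mmCIF reading through bio3d, biological
# assembly expansion from REMARK 350 operators, and PDB output for
# synthetic models (with assembly records for fixture round trips).

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Read a protein structure into a structure model
#'
#' Reads a PDB or mmCIF file via bio3d, keeps the first model's polymer
#' chains (heteroatoms and waters excluded), resolves alternate locations
#' (altloc blank or 'A'; highest occupancy on tie) and extracts the
#' backbone of every chain. Residues missing any of N, CA, C, O are
#' flagged incomplete; chains with no complete residue are dropped with a
#' warning. Biological-assembly operators (PDB REMARK 350) are parsed and
#' stored for [select_assembly].
#'
#' @param path File path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by extension; `.cif` /
#'   `.mmcif` read as mmCIF).
#' @return A [structure_model] ("asu", the deposited chains).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
    else bio3d::read.cif(path, multi = FALSE, verbose = FALSE),
    error = function(e) stop(sprintf("could not parse %s as %s: %s",
                                     path, format, conditionMessage(e))))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- " "
  chains <- list()
  for (cid in unique(at$chain)) {
    ca <- at[at$chain == cid, , drop = FALSE]
    key <- paste(ca$resno, ca$insert)
    resk <- unique(key)
    n <- length(resk)
    xyz <- lapply(BACKBONE_ATOMS, function(a) matrix(NA_real_, n, 3))
    names(xyz) <- BACKBONE_ATOMS
    resno <- integer(n); icode <- character(n); aa <- character(n)
    for (i in seq_len(n)) {
      rows <- ca[key == resk[i], , drop = FALSE]
      resno[i] <- rows$resno[1]
      icode[i] <- rows$insert[1]
      aa[i] <- bio3d::aa321(rows$resid[1])
      for (a in BACKBONE_ATOMS) {
        hit <- rows[rows$elety == a, , drop = FALSE]
        if (nrow(hit) > 1) { # altloc tie: highest occupancy, then first
          hit <- hit[order(-hit$o), , drop = FALSE][1, , drop = FALSE]
        }
        if (nrow(hit) == 1) xyz[[a]][i, ] <- c(hit$x, hit$y, hit$z)
      }
    }
    ch <- backbone_chain(cid, resno, aa, xyz$N, xyz$CA, xyz$C, xyz$O,
                         icode = icode)
    if (!any(ch$res$complete)) {
      warning(sprintf("chain %s has no complete backbone residue; dropped",
                      cid))
      next
    }
    chains[[length(chains) + 1]] <- ch
  }
  if (!length(chains)) stop("no usable polymer chains in file")
  model <- structure_model(basename(path), chains, assembly_id = "asu")
  attr(model, "assembly_ops") <- if (format == "pdb")
    .parse_remark350(path) else list()
  model
}

# parse REMARK 350 biological-assembly operators from a PDB file into
# list(assembly id -> list(chains, ops = list of list(R, t)))
.parse_remark350 <- function(path) {
  lines <- grep("^REMARK 350", readLines(path, warn = FALSE), value = TRUE)
  out <- list()
  cur <- NULL; cur_chains <- character(0); mats <- list()
  flush <- function() {
    if (!is.null(cur)) {
      ops <- lapply(mats, function(m) list(R = m[, 1:3, drop = FALSE],
                                           t = m[, 4]))
      out[[cur]] <<- list(chains = cur_chains, ops = ops)
    }
  }
  for (ln in lines) {
    if (grepl("BIOMOLECULE:", ln)) {
      flush()
      cur <- sub(".*BIOMOLECULE:\\s*", "", ln)
      cur <- gsub("\\s", "", cur)
      cur_chains <- character(0); mats <- list()
    } else if (grepl("APPLY THE FOLLOWING TO CHAINS:", ln)) {
      cc <- sub(".*CHAINS:\\s*", "", ln)
      cur_chains <- c(cur_chains,
                      trimws(strsplit(cc, ",")[[1]]))
    } else if (grepl("BIOMT[123]", ln)) {
      m <- regmatches(ln, regexec(
        "BIOMT([123])\\s+(\\d+)\\s+(\\S+)\\s+(\\S+)\\s+(\\S+)\\s+(\\S+)", ln))[[1]]
      if (length(m) == 7) {
        row <- as.integer(m[2]); op <- as.integer(m[3])
        vals <- as.numeric(m[4:7])
        if (length(mats) < op) mats[[op]] <- matrix(NA_real_, 3, 4)
        mats[[op]][row, ] <- vals
      }
    }
  }
  flush()
  out
}

#' Select or expand a biological assembly
#'
#' Applies the named assembly's symmetry operators to the deposited
#' chains, renaming copies uniquely (`A`, `A2`, `A3`, ...). `"asu"`
#' returns the deposited chains unchanged. The default assembly for
#' analysis is `"1"` when defined, else the asymmetric unit.
#'
#' @param model A [structure_model] from [read_structure].
#' @param assembly Assembly identifier (text, e.g. `"1"`) or `"asu"`.
#' @return The expanded [structure_model].
#' @export
select_assembly <- function(model, assembly = "1") {
  if (identical(assembly, "asu")) {
    model$assembly_id <- "asu"
    return(model)
  }
  if (!identical(model$assembly_id, "asu")) {
    stop("model is already assembly-expanded")
  }
  ops_all <- attr(model, "assembly_ops")
  if (is.null(ops_all) || !length(ops_all)) {
    stop("no assembly definitions present; available: (none), use \"asu\"")
  }
  if (!assembly %in% names(ops_all)) {
    stop(sprintf("unknown assembly '%s'; available: %s", assembly,
                 paste(names(ops_all), collapse = ", ")))
  }
  def <- ops_all[[assembly]]
  src <- if (length(def$chains)) def$chains else names(model$chains)
  chains <- list()
  for (k in seq_along(def$ops)) {
    op <- def$ops[[k]]
    for (cid in src) {
      if (!cid %in% names(model$chains)) next
      ch <- transform_chain(model$chains[[cid]], op$R, op$t)
      ch$chain_id <- if (k == 1) cid else paste0(cid, k)
      chains[[length(chains) + 1]] <- ch
    }
  }
  out <- structure_model(model$id, chains, assembly_id = assembly)
  out
}

#' Write a structure model as PDB
#'
#' Writes the backbone (N, CA, C, O) of every chain as ATOM records via
#' bio3d, optionally preceded by REMARK 350 assembly operators, so that
#' synthetic fixtures round-trip through [read_structure] and
#' [select_assembly].
#'
#' @param model A [structure_model].
#' @param path Output file path.
#' @param assembly_ops Optional list of 3x3 rotation / length-3
#'   translation pairs (`list(list(R=, t=), ...)`) written as assembly 1
#'   applying to all chains.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, assembly_ops = NULL) {
  xyz <- c(); resno <- c(); chain <- c(); resid <- c(); elety <- c()
  for (ch in model$chains) {
    for (i in seq_len(nrow(ch$res))) {
      for (a in BACKBONE_ATOMS) {
        p <- ch[[a]][i, ]
        if (anyNA(p)) next
        xyz <- c(xyz, p)
        resno <- c(resno, ch$res$resno[i])
        chain <- c(chain, substr(ch$chain_id, 1, 1))
        resid <- c(resid, bio3d::aa123(ch$res$aa[i]))
        elety <- c(elety, a)
      }
    }
  }
  bio3d::write.pdb(file = path, xyz = xyz, resno = resno, chain = chain,
                   resid = resid, elety = elety)
  if (!is.null(assembly_ops)) {
    body <- readLines(path, warn = FALSE)
    hdr <- c("REMARK 350 BIOMOLECULE: 1",
             sprintf("REMARK 350 APPLY THE FOLLOWING TO CHAINS: %s",
                     paste(substr(names(model$chains), 1, 1),
                           collapse = ", ")))
    for (k in seq_along(assembly_ops)) {
      op <- assembly_ops[[k]]
      for (r in 1:3) {
        hdr <- c(hdr, sprintf(
          "REMARK 350   BIOMT%d %3d%10.6f%10.6f%10.6f%15.5f",
          r, k, op$R[r, 1], op$R[r, 2], op$R[r, 3], op$t[r]))
      }
    }
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}

#' Write a fixture with its ground-truth annotation
#'
#' Writes the model as PDB and its annotation (planted layers, registers,
#' nominal periodicities) as JSON alongside.
#'
#' @param model A [structure_model] carrying an `annotation` attribute.
#' @param path PDB output path; the annotation goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(model, path) {
  write_structure(model, path)
  ann <- attr(model, "annotation")
  if (!is.null(ann)) {
    ann$params <- NULL
    jsonlite::write_json(ann, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
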