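# Internal tokenizer: strip ';' comments, split on whitespace.
.strip_comment <- function(line) sub(";.*$", "", line)
.tok <- function(line) {
  line <- trimws(.strip_comment(line))
  if (!nzchar(line)) return(character(0))
  strsplit(line, "[ \t]+")[[1]]
}

.num <- function(x) suppressWarnings(as.numeric(x))

# Canonical unordered pair key for nonbonded overrides.
.pair_key <- function(a, b) {
  ifelse(a <= b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
}

.empty_atoms <- function() {
  data.frame(index = integer(0), type = character(0), resnr = integer(0),
             resname = character(0), atomname = character(0), cgnr = integer(0),
             charge = numeric(0), mass = numeric(0), stringsAsFactors = FALSE)
}
.empty_bonds <- function() {
  data.frame(ai = integer(0), aj = integer(0), funct = integer(0),
             params_raw = character(0), stringsAsFactors = FALSE)
}
.empty_angles <- function() {
  data.frame(ai = integer(0), aj = integer(0), ak = integer(0), funct = integer(0),
             params_raw = character(0), stringsAsFactors = FALSE)
}
.empty_dihedrals <- function() {
  data.frame(ai = integer(0), aj = integer(0), ak = integer(0), al = integer(0),
             funct = integer(0), phase = numeric(0), k = numeric(0),
             mult = integer(0), params_raw = character(0), stringsAsFactors = FALSE)
}

#' Construct an empty force-field topology
#'
#' The in-memory model of a molecular topology in the GROMACS dialect:
#' global atom types (name, mass, charge, sigma, epsilon), pairwise
#' nonbonded overrides (`[ nonbond_params ]`), and named molecules each
#' carrying atoms, bonds, pairs, angles and dihedrals. Sections the model
#' does not interpret (settles, exclusions, virtual sites, ...) are kept
#' verbatim and written back unchanged.
#'
#' All indices are 1-based as in the dialect. Units follow the dialect:
#' nm for sigma, kJ/mol for epsilon and force constants, degrees for
#' dihedral phases, amu for masses, elementary charge for charges.
#'
#' @param comb_rule `"lorentz_berthelot"` (arithmetic sigma, geometric
#'   epsilon) or `"geometric"` (both geometric).
#' @return An object of class `ff_topology`.
#' @export
ff_topology <- function(comb_rule = "lorentz_berthelot") {
  stopifnot(comb_rule %in% c("lorentz_berthelot", "geometric"))
  structure(list(
    defaults = list(nbfunc = 1L, comb_rule = comb_rule, gen_pairs = "yes",
                    fudge_lj = 0.5, fudge_qq = 0.8333),
    atomtypes = data.frame(name = character(0), mass = numeric(0),
                           charge = numeric(0), sigma = numeric(0),
                           epsilon = numeric(0), stringsAsFactors = FALSE),
    nonbond_params = data.frame(type_a = character(0), type_b = character(0),
                                sigma = numeric(0), epsilon = numeric(0),
                                stringsAsFactors = FALSE),
    molecules = list(),
    preprocessor = character(0),
    other_sections = list(),
    system_name = NULL,
    system_molecules = NULL
  ), class = "ff_topology")
}

.new_molecule <- function(name, nrexcl = 3L) {
  list(name = name, nrexcl = as.integer(nrexcl),
       atoms = .empty_atoms(), bonds = .empty_bonds(), pairs = .empty_bonds(),
       angles = .empty_angles(), dihedrals = .empty_dihedrals(),
       other = list())
}

#' Parse a topology stream
#'
#' Reads the GROMACS topology dialect: `[ defaults ]`, `[ atomtypes ]`,
#' `[ nonbond_params ]`, `[ moleculetype ]` with `[ atoms ]`, `[ bonds ]`,
#' `[ pairs ]`, `[ angles ]`, `[ dihedrals ]`, plus `[ system ]` and
#' `[ molecules ]`. Unrecognized sections are preserved verbatim.
#' `#include "file"` directives are inlined literally when the file exists
#' relative to `dir`; other preprocessor lines are carried through.
#'
#' Atom-type lines are accepted with or without a bonded-type / atomic
#' number column: the particle-type letter (A/S/V/D) anchors the field
#' layout. Proper dihedrals (funct 1, 4, 9) are parsed into
#' (phase, force constant, multiplicity); other dihedral functs keep their
#' parameter text verbatim.
#'
#' @param text Character vector of lines, or a single string with newlines.
#' @param dir Directory against which `#include` paths are resolved.
#' @return An `ff_topology`.
#' @export
parse_topology <- function(text, dir = ".") {
  if (length(text) == 1 && grepl("\n", text)) text <- strsplit(text, "\n")[[1]]

  # literal #include inlining
  expand <- function(lines, depth = 0) {
    if (depth > 10) stop("#include nesting too deep")
    out <- character(0)
    for (ln in lines) {
      m <- regmatches(ln, regexec("^\\s*#include\\s+[\"<]([^\">]+)[\">]", ln))[[1]]
      if (length(m) == 2) {
        path <- file.path(dir, m[2])
        if (file.exists(path)) {
          out <- c(out, expand(readLines(path, warn = FALSE), depth + 1))
        } else {
          stop("cannot inline #include: file not found: ", m[2])
        }
      } else out <- c(out, ln)
    }
    out
  }
  text <- expand(text)

  topo <- ff_topology()
  section <- NULL
  cur_mol <- NULL
  seen_atomtypes <- FALSE
  flush_mol <- function() {
    if (!is.null(cur_mol)) topo$molecules[[cur_mol$name]] <<- cur_mol
    cur_mol <<- NULL
  }

  for (raw in text) {
    if (grepl("^\\s*#", raw)) {  # preprocessor other than #include (already inlined)
      topo$preprocessor <- c(topo$preprocessor, trimws(raw))
      next
    }
    hdr <- regmatches(raw, regexec("^\\s*\\[\\s*([A-Za-z0-9_+-]+)\\s*\\]", raw))[[1]]
    if (length(hdr) == 2) {
      section <- tolower(hdr[2])
      if (section == "moleculetype") flush_mol()
      next
    }
    f <- .tok(raw)
    if (length(f) == 0 || is.null(section)) next

    if (section == "defaults") {
      topo$defaults$nbfunc <- as.integer(f[1])
      cr <- as.integer(f[2])
      topo$defaults$comb_rule <- switch(as.character(cr),
        "2" = "lorentz_berthelot", "3" = "geometric",
        stop("unsupported combination rule: ", cr,
             " (only sigma/epsilon rules 2 and 3 are supported)"))
      if (length(f) >= 3) topo$defaults$gen_pairs <- f[3]
      if (length(f) >= 4) topo$defaults$fudge_lj <- .num(f[4])
      if (length(f) >= 5) topo$defaults$fudge_qq <- .num(f[5])
    } else if (section == "atomtypes") {
      seen_atomtypes <- TRUE
      # locate the particle-type letter to anchor the layout
      ppos <- which(toupper(f) %in% c("A", "S", "V", "D") & nchar(f) == 1)
      ppos <- ppos[ppos >= 4 & ppos <= length(f) - 2]
      if (length(ppos) == 0) stop("cannot parse atomtypes line: ", raw)
      p <- ppos[length(ppos)]
      topo$atomtypes <- rbind(topo$atomtypes, data.frame(
        name = f[1], mass = .num(f[p - 2]), charge = .num(f[p - 1]),
        sigma = .num(f[p + 1]), epsilon = .num(f[p + 2]),
        stringsAsFactors = FALSE))
    } else if (section == "nonbond_params") {
      key <- .pair_key(f[1], f[2])
      if (nrow(topo$nonbond_params) &&
          key %in% .pair_key(topo$nonbond_params$type_a, topo$nonbond_params$type_b))
        stop("duplicate nonbonded override for pair (", f[1], ", ", f[2], ")")
      topo$nonbond_params <- rbind(topo$nonbond_params, data.frame(
        type_a = f[1], type_b = f[2], sigma = .num(f[4]), epsilon = .num(f[5]),
        stringsAsFactors = FALSE))
    } else if (section == "moleculetype") {
      cur_mol <- .new_molecule(f[1], as.integer(f[2]))
    } else if (section == "system") {
      topo$system_name <- paste(f, collapse = " ")
    } else if (section == "molecules") {
      topo$system_molecules <- rbind(topo$system_molecules, data.frame(
        name = f[1], count = as.integer(f[2]), stringsAsFactors = FALSE))
    } else if (is.null(cur_mol)) {
      topo$other_sections[[section]] <- c(topo$other_sections[[section]], trimws(raw))
    } else if (section == "atoms") {
      cur_mol$atoms <- rbind(cur_mol$atoms, data.frame(
        index = as.integer(f[1]), type = f[2], resnr = as.integer(f[3]),
        resname = f[4], atomname = f[5],
        cgnr = if (length(f) >= 6) as.integer(f[6]) else as.integer(f[1]),
        charge = if (length(f) >= 7) .num(f[7]) else NA_real_,
        mass = if (length(f) >= 8) .num(f[8]) else NA_real_,
        stringsAsFactors = FALSE))
    } else if (section %in% c("bonds", "pairs")) {
      row <- data.frame(ai = as.integer(f[1]), aj = as.integer(f[2]),
                        funct = as.integer(f[3]),
                        params_raw = if (length(f) > 3)
                          paste(f[-(1:3)], collapse = " ") else NA_character_,
                        stringsAsFactors = FALSE)
      if (section == "bonds") cur_mol$bonds <- rbind(cur_mol$bonds, row)
      else cur_mol$pairs <- rbind(cur_mol$pairs, row)
    } else if (section == "angles") {
      cur_mol$angles <- rbind(cur_mol$angles, data.frame(
        ai = as.integer(f[1]), aj = as.integer(f[2]), ak = as.integer(f[3]),
        funct = as.integer(f[4]),
        params_raw = if (length(f) > 4) paste(f[-(1:4)], collapse = " ") else NA_character_,
        stringsAsFactors = FALSE))
    } else if (section == "dihedrals") {
      funct <- as.integer(f[5])
      if (funct %in% c(1L, 4L, 9L) && length(f) >= 8) {
        cur_mol$dihedrals <- rbind(cur_mol$dihedrals, data.frame(
          ai = as.integer(f[1]), aj = as.integer(f[2]), ak = as.integer(f[3]),
          al = as.integer(f[4]), funct = funct, phase = .num(f[6]),
          k = .num(f[7]), mult = as.integer(f[8]), params_raw = NA_character_,
          stringsAsFactors = FALSE))
      } else {
        cur_mol$dihedrals <- rbind(cur_mol$dihedrals, data.frame(
          ai = as.integer(f[1]), aj = as.integer(f[2]), ak = as.integer(f[3]),
          al = as.integer(f[4]), funct = funct, phase = NA_real_, k = NA_real_,
          mult = NA_integer_,
          params_raw = if (length(f) > 5) paste(f[-(1:5)], collapse = " ") else NA_character_,
          stringsAsFactors = FALSE))
      }
    } else {
      cur_mol$other[[section]] <- c(cur_mol$other[[section]], trimws(raw))
    }
  }
  flush_mol()

  if (!seen_atomtypes) stop("topology stream has no [ atomtypes ] section")
  if (length(topo$molecules) == 0) stop("topology stream has no molecule block")

  # resolve atom types; unresolved is a hard error naming the token
  for (mol in topo$molecules) {
    missing <- setdiff(unique(mol$atoms$type), topo$atomtypes$name)
    if (length(missing))
      stop("molecule '", mol$name, "' references undefined atom type(s): ",
           paste(missing, collapse = ", "))
  }
  topo
}

#' Parse a topology file
#'
#' @param path Path to a `.top`/`.itp`-style file.
#' @return An `ff_topology`.
#' @export
parse_topology_file <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  parse_topology(readLines(path, warn = FALSE), dir = dirname(path))
}

.fmt <- function(x, digits = 8) formatC(x, format = "g", digits = digits)

#' Write a topology to text
#'
#' Deterministic section order: preprocessor lines, defaults, atomtypes,
#' nonbond_params, preserved global sections, each molecule (atoms, bonds,
#' pairs, angles, dihedrals, preserved sections), system, molecules.
#' Floats are written with 8 significant digits, so a parse -> write ->
#' parse round trip is a semantic fixed point.
#'
#' @param topo An `ff_topology`.
#' @return Character vector of lines.
#' @export
write_topology <- function(topo) {
  stopifnot(inherits(topo, "ff_topology"))
  out <- character(0)
  emit <- function(...) out <<- c(out, ...)
  if (length(topo$preprocessor)) emit(topo$preprocessor, "")

  d <- topo$defaults
  emit("[ defaults ]",
       "; nbfunc  comb-rule  gen-pairs  fudgeLJ  fudgeQQ",
       sprintf("%d  %d  %s  %s  %s", d$nbfunc,
               if (d$comb_rule == "lorentz_berthelot") 2L else 3L,
               d$gen_pairs, .fmt(d$fudge_lj), .fmt(d$fudge_qq)), "")

  emit("[ atomtypes ]", "; name  mass  charge  ptype  sigma  epsilon")
  at <- topo$atomtypes
  for (i in seq_len(nrow(at)))
    emit(sprintf("%-10s %12s %10s  A %14s %14s", at$name[i], .fmt(at$mass[i]),
                 .fmt(at$charge[i]), .fmt(at$sigma[i]), .fmt(at$epsilon[i])))
  emit("")

  nb <- topo$nonbond_params
  if (!is.null(nb) && nrow(nb)) {
    emit("[ nonbond_params ]", "; typeA  typeB  func  sigma  epsilon")
    for (i in seq_len(nrow(nb)))
      emit(sprintf("%-12s %-12s 1 %14s %14s", nb$type_a[i], nb$type_b[i],
                   .fmt(nb$sigma[i]), .fmt(nb$epsilon[i])))
    emit("")
  }

  for (sec in names(topo$other_sections))
    emit(sprintf("[ %s ]", sec), topo$other_sections[[sec]], "")

  for (mol in topo$molecules) {
    emit("[ moleculetype ]", sprintf("%s  %d", mol$name, mol$nrexcl), "")
    a <- mol$atoms
    emit("[ atoms ]", ";  nr  type  resnr  residue  atom  cgnr  charge  mass")
    for (i in seq_len(nrow(a))) {
      line <- sprintf("%6d %-10s %5d %-5s %-6s %5d", a$index[i], a$type[i],
                      a$resnr[i], a$resname[i], a$atomname[i], a$cgnr[i])
      if (!is.na(a$charge[i])) line <- paste0(line, sprintf(" %12s", .fmt(a$charge[i])))
      if (!is.na(a$mass[i])) line <- paste0(line, sprintf(" %12s", .fmt(a$mass[i])))
      emit(line)
    }
    emit("")
    emit_bondlike <- function(df, name, nidx) {
      if (!nrow(df)) return()
      emit(sprintf("[ %s ]", name))
      for (i in seq_len(nrow(df))) {
        idx <- unlist(df[i, seq_len(nidx)])
        line <- paste(c(sprintf("%6d", idx), sprintf("%3d", df$funct[i])), collapse = " ")
        if (!is.na(df$params_raw[i])) line <- paste(line, df$params_raw[i])
        emit(line)
      }
      emit("")
    }
    emit_bondlike(mol$bonds, "bonds", 2)
    emit_bondlike(mol$pairs, "pairs", 2)
    emit_bondlike(mol$angles, "angles", 3)
    dh <- mol$dihedrals
    if (nrow(dh)) {
      emit("[ dihedrals ]", ";  ai  aj  ak  al  funct  phase  k  mult")
      for (i in seq_len(nrow(dh))) {
        line <- sprintf("%6d %6d %6d %6d %3d", dh$ai[i], dh$aj[i], dh$ak[i],
                        dh$al[i], dh$funct[i])
        if (!is.na(dh$k[i])) {
          line <- paste0(line, sprintf(" %12s %12s %3d", .fmt(dh$phase[i]),
                                       .fmt(dh$k[i]), dh$mult[i]))
        } else if (!is.na(dh$params_raw[i])) {
          line <- paste(line, dh$params_raw[i])
        }
        emit(line)
      }
      emit("")
    }
    for (sec in names(mol$other))
      emit(sprintf("[ %s ]", sec), mol$other[[sec]], "")
  }

  if (!is.null(topo$system_name)) emit("[ system ]", topo$system_name, "")
  if (!is.null(topo$system_molecules)) {
    emit("[ molecules ]")
    for (i in seq_len(nrow(topo$system_molecules)))
      emit(sprintf("%-12s %6d", topo$system_molecules$name[i],
                   topo$system_molecules$count[i]))
    emit("")
  }
  out
}

#' Write a topology to a file (atomically)
#'
#' @param topo An `ff_topology`.
#' @param path Output path; written via a temporary file and rename.
#' @export
write_topology_file <- function(topo, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writeLines(write_topology(topo), tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Validate a topology against its structural invariants
#'
#' Checks: atom types resolve; sigma/epsilon/mass non-negative; atom
#' indices unique and 1..N per molecule; per-molecule net charge an
#' integer within 1e-6 e; proper-dihedral multiplicity >= 1; at most one
#' nonbonded override per unordered type pair.
#'
#' @param topo An `ff_topology`.
#' @return data.frame with columns `record`, `rule`, `message`; zero rows
#'   iff the topology is valid.
#' @export
validate_topology <- function(topo) {
  v <- list()
  bad <- function(record, rule, message)
    v[[length(v) + 1]] <<- data.frame(record = record, rule = rule,
                                      message = message, stringsAsFactors = FALSE)
  at <- topo$atomtypes
  for (i in seq_len(nrow(at))) {
    if (is.na(at$mass[i]) || at$mass[i] < 0)
      bad(at$name[i], "atomtype_mass", "mass must be >= 0")
    if (is.na(at$sigma[i]) || at$sigma[i] < 0)
      bad(at$name[i], "atomtype_sigma", "sigma must be >= 0")
    if (is.na(at$epsilon[i]) || at$epsilon[i] < 0)
      bad(at$name[i], "atomtype_epsilon", "epsilon must be >= 0")
  }
  if (anyDuplicated(at$name))
    bad(paste(at$name[duplicated(at$name)], collapse = ","), "atomtype_unique",
        "duplicate atom type name")
  nb <- topo$nonbond_params
  if (!is.null(nb) && nrow(nb)) {
    keys <- .pair_key(nb$type_a, nb$type_b)
    if (anyDuplicated(keys))
      bad("nonbond_params", "override_unique",
          "more than one override for an unordered type pair")
  }
  for (mol in topo$molecules) {
    a <- mol$atoms
    missing <- setdiff(unique(a$type), at$name)
    if (length(missing))
      bad(mol$name, "type_resolves",
          paste("undefined atom type(s):", paste(missing, collapse = ", ")))
    if (anyDuplicated(a$index) || !identical(sort(a$index), seq_len(nrow(a))))
      bad(mol$name, "atom_indices", "atom indices must be unique 1..N")
    q <- ifelse(is.na(a$charge), at$charge[match(a$type, at$name)], a$charge)
    net <- sum(q)
    if (is.na(net) || abs(net - round(net)) > 1e-6)
      bad(mol$name, "net_charge",
          sprintf("net charge %.6f is not an integer within 1e-6 e", net))
    dh <- mol$dihedrals
    prop <- dh$funct %in% c(1L, 4L, 9L) & !is.na(dh$mult)
    if (any(prop & dh$mult < 1))
      bad(mol$name, "dihedral_multiplicity", "proper dihedral multiplicity must be >= 1")
  }
  if (length(v)) do.call(rbind, v)
  else data.frame(record = character(0), rule = character(0),
                  message = character(0), stringsAsFactors = FALSE)
}

#' @export
print.ff_topology <- function(x, ...) {
  cat("<ff_topology>\n")
  cat("  combination rule:", x$defaults$comb_rule, "\n")
  cat("  atom types:", nrow(x$atomtypes), "\n")
  cat("  nonbonded overrides:", nrow(x$nonbond_params), "\n")
  for (m in x$molecules)
    cat(sprintf("  molecule %-12s %5d atoms, %d bonds, %d dihedrals\n",
                m$name, nrow(m$atoms), nrow(m$bonds), nrow(m$dihedrals)))
  invisible(x)
}

# Effective per-atom charge/mass: explicit value if present, else the
# atom-type default.
.atom_charges <- function(topo, mol) {
  at <- topo$atomtypes
  ifelse(is.na(mol$atoms$charge), at$charge[match(mol$atoms$type, at$name)],
         mol$atoms$charge)
}
.atom_masses <- function(topo, mol) {
  at <- topo$atomtypes
  ifelse(is.na(mol$atoms$mass), at$mass[match(mol$atoms$type, at$name)],
         mol$atoms$mass)
}

# Look up a nonbonded override for an unordered type pair; NULL if none.
.lookup_override <- function(topo, a, b) {
  nb <- topo$nonbond_params
  if (is.null(nb) || !nrow(nb)) return(NULL)
  hit <- which(.pair_key(nb$type_a, nb$type_b) == .pair_key(a, b))
  if (!length(hit)) return(NULL)
  list(sigma = nb$sigma[hit[1]], epsilon = nb$epsilon[hit[1]])
}
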