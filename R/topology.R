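# GROMACS TOP/ITP mass editing.
#
# Only the mass column of the matching water [atoms] block is rewritten;
# every other byte of the file is preserved, so diffs against the source
# topology show exactly the three mass edits. Atom roles are positional
# (atom 1 = O, atoms 2-3 = H), matching the conventional ordering of rigid
# 3-site water blocks.

.strip_comment <- function(line) sub(";.*$", "", line)

.is_section_header <- function(line) {
  grepl("^\\s*\\[\\s*[A-Za-z_]+\\s*\\]\\s*$", .strip_comment(line))
}

.section_name <- function(line) {
  m <- regmatches(line, regexec("\\[\\s*([A-Za-z_]+)\\s*\\]", line))[[1]]
  tolower(m[2])
}

.format_mass <- function(x) {
  format(x, trim = TRUE, scientific = FALSE, digits = 15)
}

# Replace the k-th whitespace-separated token of the pre-comment part of a
# line, preserving all whitespace and any trailing comment.
.replace_token <- function(line, k, replacement) {
  comment_at <- regexpr(";", line, fixed = TRUE)
  code <- if (comment_at > 0) substr(line, 1L, comment_at - 1L) else line
  tail <- if (comment_at > 0) substring(line, comment_at) else ""
  toks <- gregexpr("[^[:space:]]+", code)[[1]]
  if (length(toks) < k || toks[1] == -1) {
    return(NULL)
  }
  start <- toks[k]
  end <- start + attr(toks, "match.length")[k] - 1L
  paste0(substr(code, 1L, start - 1L), replacement,
         substring(code, end + 1L), tail)
}

#' Rewrite the water masses in a GROMACS topology
#'
#' Finds the `[moleculetype]` whose name matches `molecule_name`, checks that
#' its `[atoms]` block holds exactly 3 atoms (O, H, H by position), and
#' rewrites the mass column (8th field) with the site masses of `masses`.
#' All other bytes -- comments, spacing, every other section -- are preserved,
#' and the operation is idempotent.
#'
#' @param topology_text topology content: a single string or a character
#'   vector of lines
#' @param masses a [water_masses()] object; the oxygen mass goes to atom 1,
#'   the hydrogen mass to atoms 2 and 3
#' @param molecule_name moleculetype name to edit (default `"SOL"`)
#' @return Topology text in the same shape as the input (single string in,
#'   single string out).
#' @export
#' @examples
#' itp <- c("[ moleculetype ]", "SOL 2", "[ atoms ]",
#'          "1 OW 1 SOL OW  1 -0.834 15.9994",
#'          "2 HW 1 SOL HW1 1  0.417 1.008",
#'          "3 HW 1 SOL HW2 1  0.417 1.008")
#' cat(apply_to_topology(itp, fast_water_masses()), sep = "\n")
apply_to_topology <- function(topology_text, masses, molecule_name = "SOL") {
  stopifnot(inherits(masses, "water_masses"), is.character(topology_text))
  single <- length(topology_text) == 1L && grepl("\n", topology_text,
                                                 fixed = TRUE)
  lines <- if (single) strsplit(topology_text, "\n", fixed = TRUE)[[1]]
           else topology_text

  # locate sections: for each line, the active section and, within
  # moleculetype sections, the molecule name (first token of first data line)
  section <- NA_character_
  current_mol <- NA_character_
  atom_lines <- integer(0)
  found_molecule <- FALSE
  in_target_atoms <- FALSE
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (.is_section_header(line)) {
      section <- .section_name(.strip_comment(line))
      if (section == "moleculetype") current_mol <- NA_character_
      in_target_atoms <- section == "atoms" && identical(current_mol,
                                                         molecule_name)
      next
    }
    code <- trimws(.strip_comment(line))
    if (!nzchar(code)) next
    if (identical(section, "moleculetype") && is.na(current_mol)) {
      current_mol <- strsplit(code, "[[:space:]]+")[[1]][1]
      if (identical(current_mol, molecule_name)) found_molecule <- TRUE
    } else if (in_target_atoms) {
      atom_lines <- c(atom_lines, i)
    }
  }

  if (!found_molecule) {
    stop("missing molecule: no [moleculetype] named '", molecule_name,
         "' in topology", call. = FALSE)
  }
  if (length(atom_lines) != 3L) {
    stop("unsupported topology: [atoms] block of '", molecule_name,
         "' has ", length(atom_lines), " atoms, expected 3", call. = FALSE)
  }

  new_masses <- c(masses$m_O, masses$m_H, masses$m_H)
  for (j in seq_along(atom_lines)) {
    i <- atom_lines[j]
    replaced <- .replace_token(lines[i], 8L, .format_mass(new_masses[j]))
    if (is.null(replaced)) {
      stop("unsupported topology: atom line ", i, " has fewer than 8 fields ",
           "(no mass column)", call. = FALSE)
    }
    lines[i] <- replaced
  }
  if (single) paste(lines, collapse = "\n") else lines
}

#' Edit the water masses of a topology file
#'
#' File-level wrapper around [apply_to_topology()].
#'
#' @param infile input TOP/ITP path
#' @param outfile output path (may equal `infile`)
#' @inheritParams apply_to_topology
#' @return `outfile`, invisibly.
#' @export
edit_topology_file <- function(infile, outfile, masses,
                               molecule_name = "SOL") {
  lines <- readLines(infile, warn = FALSE)
  out <- apply_to_topology(lines, masses, molecule_name)
  writeLines(out, outfile)
  invisible(outfile)
}
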