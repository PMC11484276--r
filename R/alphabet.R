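## Residue alphabets shared across the package.

#' @keywords internal
CANONICAL_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Ambiguity / nonstandard codes tolerated on input. U (selenocysteine) and
## O (pyrrolysine) are genuine residues; B, Z, X, J are ambiguity codes and
## '*' a stop. The default ambiguity set used for sequence removal is the
## latter group only (see drop_ambiguous).
#' @keywords internal
NONSTANDARD_AA <- c("B", "Z", "X", "J", "U", "O", "*")

#' @keywords internal
RESIDUE_ALPHABET <- c(CANONICAL_AA, NONSTANDARD_AA)

#' @keywords internal
GAP_CHAR <- "-"

## Lowercase 'x' marks a residue masked near an indel. Only legal inside
## alignments, never in unaligned sequences; invisible to conservation counts.
#' @keywords internal
MASK_CHAR <- "x"

#' Default ambiguity set used when discarding sequences
#'
#' B, Z, X and J are amino-acid ambiguity codes and `*` a stop; U and O are
#' genuine (if rare) residues and are deliberately not in the default set.
#'
#' @return Character vector of single-letter codes.
#' @export
default_ambiguous_set <- function() c("B", "Z", "X", "J", "*")

#' @keywords internal
AA_THREE_TO_ONE <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
  Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
  Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
  Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V",
  Sec = "U", Pyl = "O", Asx = "B", Glx = "Z", Xaa = "X", Xle = "J"
)
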