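# Sequence architecture of piggyBac-derived elements.
#
# MER85 layout (element-oriented, 0-based offsets within the 140-bp span,
# which here includes the 5' target-site duplication):
#   [0,4)    TTAA target-site duplication (TSD)
#   [4,17)   5' terminal inverted repeat (TIR), 13 bp
#   [17,20)  3-bp spacer
#   [20,36)  imperfect 16-bp internal palindrome GTTCCAtTAtTGGAAC
#   [36,127) internal sequence
#   [127,140) 3' TIR (reverse complement of the 5' TIR)
# A second TTAA copy sits immediately 3' of the element in the flank.
#
# The full-length PGBD3-like transposon (2.5 kb) carries three copies of the
# same palindrome: just internal to the 5' TIR, 59 bp upstream of the
# transposase ORF start, and 75 bp downstream of the ORF stop / 114 bp
# upstream of the 3' TIR.

TSD_SEQ <- "TTAA"
TIR5_CONSENSUS <- "CCCTAGAAAGATA"   # 13 bp, piggyBac-family terminal repeat
PALINDROME_CONSENSUS <- "GTTCCATTATTGGAAC"
MER85_SPACER <- "GCA"
MER85_LENGTH <- 140L

# Fixed synthetic internal sequence (91 bp), free of TSD/TIR/palindrome/motif
# matches on either strand so planted features stay unambiguous.
MER85_INTERNAL <- paste0(
  "GTATACTAGCTCTCAGTGTTTCAGGATTTATGAGTCGAACTACGTCGAGCAAACAAGCAGCTAAAGATTC",
  "AATCCGAGTCGGAAGGACCCG"
)

PGBD3_FILLER_A <- paste0(  # 389 bp between palindrome 1 and palindrome 2
  "AGATAATCCTAGTACTGGAAGAGGGCATAAGCCCGACTAAACGCAGCGGATTTGAGTCGGGAAAGCTCCT",
  "ATGTCATAACACAGCTGGACCCCACTCCCAAAACCTCTCTGATGGTGAGCATTTGTTGTTTATAATGGAA",
  "GCCCAAATTCTGGCAGTTCTATTACGCTTCGTGTCACGGGCTCAGGAGAGAGCCTGCTAACTCTCAAGTT",
  "CTAGTCGCGTACTACCGCGATCAGATGAGCATTGCGAGTTGGCGTAGATGCGATGTTACAGCAGGAAGTG",
  "TAAGCGAGCCTACGGGTGAGGACGCGATCCGAGCTCTTGGTGGCAGGATTGGATAGTATAGCCATACCCA",
  "AATAGAACGATTCCAGGTTTTGGTCCTCTTTTCTAGGGC"
)
PGBD3_GAP_59 <- "GAGTAATACGACCTCCGAGCTCCTGCCACAAAATATAGAATTAGAGCGACAACCCCGGG"
PGBD3_ORF <- paste0(  # 1782 bp synthetic stand-in for the transposase ORF
  "CGCAATCCTGCGGAAAGTCGGAGTCCGATTATAGACACCAGCCATCTTGCGTGTCTACCGTTCTCCCAGA",
  "GGTAGGGCCCGGAAGCTGCGTGACGCGTAGCGCTCACTCCGATAGTAGGGTCGCGCGCTAGGCGTTCTGA",
  "ACATCACTCTAAGCGTCGGATGCTTGAAAAACACGTGCAGGTAGCACGTGGAAGCTGCTCGACAAGAAAG",
  "TTTCTCATCCACTCCGAAACTGACACCGAGCATTCTGGTCTTCTGTGACACCCGCGACGCGATCGCAACG",
  "CGAAGGCACCGGCCCATCGGCATCCAAACAGGCACTGGCCTTCATCAGTCCGGCCGCCACAAGGCACGAG",
  "ATGACGCAGCGCAGCGACTCCAAACAGGAGACCTCGTCTGAGCGCGTCAATGACTAAAGTATACCCATCA",
  "AAACACCCCCGGCCGAAAACATATTTCAATAGGTATAGGGGACTAAGGAGGGCTCGCTCCCCCTTGAATT",
  "CCGGCCTGTTTGTCGCTCAATTTTTCTTGCAGCAGGAGTCCCACCGTCTTCAACTACCGACATGTCCGAG",
  "TTTGGGATGGTACTCCGGATTGACCAGGTAATGTTCCCGACATTTCCTATAGATACGGTTTCCTACGTTT",
  "GCAATCTCCTGCGTAGTCATTGCCTTAGCCGCCCCGCTGTTCTTGCTCGGTCTACAGGTCTTATCACCGG",
  "CTTTCGATCGCTACCCCACGGTCCAACCGGACCGCCTTGAGCTGGGAAGATAAAACAGAAAGGGATTGGA",
  "TTGGATTTACGGAAGTTGGTCTGACACCATCAATAATATCCGTGACCTAGGCGTTTCAGCGCAGGAGTTC",
  "CAGAGGCACTCACTTCATCCGCAGCGTATAAGGACTGAAGAGGCTTCCATGGTAGTGCCGAGTTGGGGAC",
  "ACAGAACCCTTCGACGAAGGCAAATCGTATATCAAACTGGAACACGATCTCGATTATCCCGTCCAGGGAT",
  "CTACCTATGCAGGATAACGGTCCTATCTTCTGTCCGTACGGGTTATACTTACACGAAAAAGATTGGTCGC",
  "CTTGATGATCATCGTGACCTGTACCACGGCCTTATTCACCGGATTTCCTTCTGGTTCCTATAGGTACCTC",
  "GGTAAGGCGATGCTTTCCTAACAATTGGATTGATCGAGCCGGTGTAGTCCAGCAAGTGCCAACTGATCGA",
  "ACTTCCTATCGCAGTCTGCTTGATACTCGTATCTGACGTCTATGCCTCGAGAGAGACGCTATTGTGGCTC",
  "CATTGCACGAGAGCCTTAGCAGGACGATGCTGGGAACGACCTGCTGGAAATGCGCACTGTCCTCGGTACA",
  "ACTCAAAATCTCACGCTGTAATCTTAGGCAATGCTGAATAAGTGTAACTTCCAGATATCGACCCTTTGGC",
  "CTATACCTACATGGGTTGTACTGCGCATCTTGCGGGGGAGACTGGGAATGAGGTTCCTCGCCCTCCAGGG",
  "CTAGTCCACCACCAAAGGATCCGCACACGATCGGGCTATCCGGGTGGTGTGGAGGCGGCGCTGGCACCCA",
  "TTTCTCACATACGAGCACCATCAGGGAACGGGCACCTCAGGGCGACTAACATAAACCTGAAGGTTGAAGG",
  "ATCAACTACACCCTGAGTCTCGCCCTCAGGACACAAAATAACGCAGCCAATGGCTTGAACGAGCAAGCGA",
  "AAACATGCTGCGAATAAATGGCACTTGCATCACTGCTCTTGATAGGGTAGCCTGACGCCAGGGAAGTGGC",
  "GTGCTATCGTTGACGCGCCGGTAGCCTTCCCT"
)
PGBD3_GAP_75 <- paste0(
  "CCGTATTTCAGGACCACTGGACAATCTATTCTATATACCTAGCTGACCCATCTTGCATAAATAGAGACGG",
  "GGTTG"
)
PGBD3_GAP_114 <- paste0(
  "ACTAGCATGTGAGGCGCACAGCTTCCATTTAGAAGGAGTGTACTCCAGTAATCAGGATCCTGAGCAGACA",
  "GGTGTGATCGCACTACAAGCCGATGCTGTCGTTTCCCTGTAGGC"
)

#' Element architecture model for MER85/PGBD3 annotation
#'
#' Bundles the sequence constants of the piggyBac-derived element family:
#' the TTAA target-site duplication, the 13-bp terminal inverted repeat
#' consensus, the imperfect 16-bp internal palindrome `GTTCCAtTAtTGGAAC`
#' located 3 bp internal to the 5' TIR, and the 140-bp MER85 reference
#' length.
#'
#' @param tsd_seq Target-site duplication sequence (default `"TTAA"`).
#' @param tir5 13-bp 5' TIR consensus; the 3' TIR is its reverse complement.
#' @param palindrome 16-bp internal palindrome consensus.
#' @param spacer_5prime Spacer length between the 5' TIR and the palindrome.
#' @param mer85_length Reference MER85 length in bp (including the 5' TSD).
#' @return A list of class `element_model`.
#' @export
element_model <- function(tsd_seq = TSD_SEQ,
                          tir5 = TIR5_CONSENSUS,
                          palindrome = PALINDROME_CONSENSUS,
                          spacer_5prime = 3L,
                          mer85_length = MER85_LENGTH) {
  stopifnot(nchar(palindrome) == 16L, nchar(tir5) == 13L)
  # the palindrome arms must be (imperfect) reverse complements of each other
  arm_l <- substr(palindrome, 1, 6)
  arm_r <- substr(palindrome, 11, 16)
  if (hamming(arm_l, revcomp(arm_r)) != 0) {
    abort("palindrome arms are not reverse complements")
  }
  structure(
    list(
      tsd_seq = tsd_seq,
      tir_length = nchar(tir5),
      tir5 = tir5,
      tir3 = revcomp(tir5),
      palindrome = palindrome,
      spacer_5prime = as.integer(spacer_5prime),
      mer85_length = as.integer(mer85_length)
    ),
    class = "element_model"
  )
}

#' Consensus sequence of a synthetic MER85 element
#'
#' Assembles the 140-bp MER85 layout from [element_model()] constants:
#' TSD + 5' TIR + 3-bp spacer + palindrome + 91-bp internal sequence +
#' 3' TIR.
#'
#' @param model An [element_model()].
#' @return A single character string of length 140.
#' @export
mer85_consensus <- function(model = element_model()) {
  seq <- paste0(model$tsd_seq, model$tir5, MER85_SPACER, model$palindrome,
                MER85_INTERNAL, model$tir3)
  stopifnot(nchar(seq) == model$mer85_length)
  seq
}

#' Consensus sequence of a synthetic full-length PGBD3-like transposon
#'
#' A 2,500-bp element carrying three copies of the internal palindrome: one
#' 3 bp internal to the 5' TIR, one ending 59 bp upstream of the transposase
#' ORF start, and one 75 bp downstream of the ORF stop (114 bp upstream of
#' the 3' TIR).
#'
#' @param model An [element_model()].
#' @return A single character string of length 2500.
#' @export
pgbd3_consensus <- function(model = element_model()) {
  seq <- paste0(model$tsd_seq, model$tir5, MER85_SPACER, model$palindrome,
                PGBD3_FILLER_A, model$palindrome, PGBD3_GAP_59, PGBD3_ORF,
                PGBD3_GAP_75, model$palindrome, PGBD3_GAP_114, model$tir3)
  stopifnot(nchar(seq) == 2500L)
  seq
}

# Truth offsets (0-based, element-oriented) of planted features within the
# consensus layouts; used by the generator to emit truth tables.
mer85_truth_offsets <- function(model = element_model()) {
  tl <- model$tir_length
  pal_start <- 4L + tl + model$spacer_5prime
  list(
    tsd = c(0L, 4L),
    tir5 = c(4L, 4L + tl),
    palindrome = c(pal_start, pal_start + 16L),
    tir3 = c(model$mer85_length - tl, model$mer85_length)
  )
}
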