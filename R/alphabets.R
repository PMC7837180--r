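# Residue alphabets shared across modules. Protein sequences admit the 20
# standard amino acids plus the ambiguity code X; nucleotide sequences
# A/C/G/T plus N. X and N never count as matches downstream.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
PROTEIN_ALPHABET <- c(AA20, "X")
NUCLEOTIDE_ALPHABET <- c("A", "C", "G", "T", "N")
MSA_SYMBOLS <- c(PROTEIN_ALPHABET, "-")
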