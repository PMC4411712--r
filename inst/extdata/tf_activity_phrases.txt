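# Default phrase list matched (case-insensitively, as substrings) against
# Pfam and GO descriptions to flag transcription-factor activity. One phrase
# per line; '#' lines are comments. Users may supply their own file.
transcription factor activity
sequence-specific dna binding transcription factor activity
dna-binding transcription factor activity
rna polymerase ii transcription factor activity
transcription regulatory region dna binding
sequence-specific dna binding
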