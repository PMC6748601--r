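# Fixed synthetic germline scaffolds for the repertoire simulator.
#
# These are SYNTHETIC sequences (random draws frozen as constants), not
# transcriptions of real IGHV/IGKV/IGLV genes: the analysis under test is
# purely positional, so only the combinatorial structure matters — distinct
# V scaffolds with their own CDR1/CDR2 lengths, a conserved Cys at IMGT
# position 104, and J tails opening with the conserved Trp (heavy) / Phe
# (light) at 118.  Layout per V: fw1 = positions 1-26, cdr1 from 27,
# fw2 = 39-55, cdr2 from 56, fw3 = 66-104; J = positions 118-128.

GERMLINE_V <- list(
  heavy = list(
    list(id = "IGHV1", fw1 = "NTPSCQGWRIESFSTHPAGMMPFRDV", cdr1 = "DYSVKQRK", fw2 = "VQHFVRNVSAIEQNNHQ", cdr2 = "YEWFLST", fw3 = "KLPSPGGDPWMPTGTIKTEVTYGRPMKGNVQWPQVITQC"),
    list(id = "IGHV2", fw1 = "APDASCNHYKAMPPHVMSKPCVCFML", cdr1 = "LWAEDLW", fw2 = "TEYGCEIEDMEHFYSVN", cdr2 = "AVKYIDN", fw3 = "LGAMPSCSDQWAAPIHEDWIVATECPLDEDNECCNIREC"),
    list(id = "IGHV3", fw1 = "KQSVVEARFQMKDVLENPLWFQNSVS", cdr1 = "WNTKYFIL", fw2 = "VINLCMWHTRVTNEIKK", cdr2 = "KISSPKL", fw3 = "GPDCTCTHPCRPNAESICIMWATAAMKYPHERKKSCIGC"),
    list(id = "IGHV4", fw1 = "DPHHGSPVGWFTVMMVSENAKHCYNC", cdr1 = "VPPFAWN", fw2 = "ASMGSEIGWDWSVHSNM", cdr2 = "TQDHNAN", fw3 = "QELTIQVNWFFDLDAEHKPEEDCFFFANCQVYAKMWVRC"),
    list(id = "IGHV5", fw1 = "FSMFKFPKLVLYKHVISLHRYEYAQR", cdr1 = "ERVQHDKG", fw2 = "CRQMQIYKCAVVGCDTK", cdr2 = "VWQCGSK", fw3 = "AVEPCSHDGANWCDTILLWFNWRHMWPFETNWFVAVDWC")
  ),
  light = list(
    list(id = "IGLV1", fw1 = "AGGCITSYHHEITLQYGFILTIYECW", cdr1 = "MHMNAMT", fw2 = "PHHSWRGIILPYRVLTN", cdr2 = "QIDTNWCL", fw3 = "KRTVTSQYIAYHLVGLLKSGINCEKTEPSIWQRIQWDSC"),
    list(id = "IGLV2", fw1 = "YIIASDAIRYKVAVHWHDGPVKEGMI", cdr1 = "PRRRPDDM", fw2 = "QHIGNDKMNSFGRIEQL", cdr2 = "WMDESNL", fw3 = "WLFYTRESYMGHCMQPEPMSHNYYNTVNNMGMQLWCIWC"),
    list(id = "IGLV3", fw1 = "QHQQLGSGGQLSYPYSTSGRWTLYCI", cdr1 = "QLVFDWIY", fw2 = "HKCTFEKVAKFLWRNCC", cdr2 = "NCITDMD", fw3 = "NCNFGYESFTFVMHRKLWPSWVGYPGNKPIKIYNYRWNC"),
    list(id = "IGLV4", fw1 = "HWQWWTCLNRLVDNRGISGWPCSNSQ", cdr1 = "DQQGRYGV", fw2 = "GFHCEFYNSAAYISQSW", cdr2 = "FNGYCVK", fw3 = "FWCCGGDNPMGNLCEAINHNQIEAEMVTRAQVLASAAKC"),
    list(id = "IGLV5", fw1 = "VAMWKWGHHATCLEQIFPNQVFWVNM", cdr1 = "SWVVFHN", fw2 = "SASSCLRCRWACVPQMD", cdr2 = "SNEAMTT", fw3 = "EGRARNNGAEGIHVLHHETHMPDSIYVECNWMACAVVLC")
  )
)

GERMLINE_J <- list(
  heavy = c(IGHJ1 = "WMEPAMAGPLE", IGHJ2 = "WCPLYLDVNQF", IGHJ3 = "WARLRLHFPNF"),
  light = c(IGLJ1 = "FEGKLNGITVS", IGLJ2 = "FDWHVIEHGNF", IGLJ3 = "FRNQRRMCFAF")
)

# positions + residues of one V scaffold, in IMGT order
.germline_v_map <- function(v) {
  fw1 <- strsplit(v$fw1, "")[[1]]
  cdr1 <- strsplit(v$cdr1, "")[[1]]
  fw2 <- strsplit(v$fw2, "")[[1]]
  cdr2 <- strsplit(v$cdr2, "")[[1]]
  fw3 <- strsplit(v$fw3, "")[[1]]
  list(
    positions = c(as.character(1:26),
                  as.character(seq(27L, length.out = length(cdr1))),
                  as.character(39:55),
                  as.character(seq(56L, length.out = length(cdr2))),
                  as.character(66:104)),
    residues = c(fw1, cdr1, fw2, cdr2, fw3)
  )
}
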