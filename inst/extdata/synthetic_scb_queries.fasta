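>synthetic_receptor_query synthetic ScbR-like stand-in
MSAQLFGTPDGCRRFMFDAVRSGNYFHFPSKERIPPFLRTIADEGMGQQYQLYARGFIAETGATCPIRVE
LEFESGFNYSEHQELVRPGRFAHLPHQPDLKTAHSGFQTSARAYPHADITDGSTHWYRGPSNGGPYFEFW
AARVNGSIATTTATQITDNEIAISAAGHGLDPNDVMLNIAMKRDHEAATAVPPVLFASRKASRQAHGYVA
RDKGA
>synthetic_synthase_query synthetic ScbA-like stand-in
MATATALGTPAEGPEEETLIAPDDVGLAILATTETRFISLFETIAQLEGLGAHRETLRQSGSRTLTAQGQ
NLDPSIPRLGGPPTNQRRLLEVARFNGLTRTTFIHRATFESTRGGNATRAYRPDAPSDGGSRTLDFGGCV
PLFHGMLWTLNQERRADRLKITFLSSLAPCRALVTPAMVVRNFATFRVHTRGAAMGLVLERLGNLMTLVM
GGLAPDINAALMKLLAQEAIPAVSTAMDMVAGRIEVGEVSTYAFLQGEDDLFGGPLQLRAATEGDTVVAL
IARATDSKVAIEVDMLAVRAGKSAAFGRDP
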