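# Synthetic 41-gene epigenetic-regulator registry.
# Genes with published panel membership and functional category are listed
# under their canonical symbols; the full 41-gene panel subset is not
# public, so the remainder are SYNTHETIC placeholder symbols (EPI_*) that
# bring the registry to 41 entries with category proportions matching the
# published breakdown (histone modification largest, then chromatin
# remodeling, DNA methylation/demethylation, miRNA processing).  Replace
# the placeholders with your own panel's gene list for real analyses.
gene	category
MECOM	HISTONE_MODIFICATION
KMT2D	HISTONE_MODIFICATION
SETD2	HISTONE_MODIFICATION
CREBBP	HISTONE_MODIFICATION
KMT2A	HISTONE_MODIFICATION
EPI_HM01	HISTONE_MODIFICATION
EPI_HM02	HISTONE_MODIFICATION
EPI_HM03	HISTONE_MODIFICATION
EPI_HM04	HISTONE_MODIFICATION
EPI_HM05	HISTONE_MODIFICATION
EPI_HM06	HISTONE_MODIFICATION
EPI_HM07	HISTONE_MODIFICATION
EPI_HM08	HISTONE_MODIFICATION
EPI_HM09	HISTONE_MODIFICATION
EPI_HM10	HISTONE_MODIFICATION
EPI_HM11	HISTONE_MODIFICATION
EPI_HM12	HISTONE_MODIFICATION
EPI_HM13	HISTONE_MODIFICATION
ARID1B	CHROMATIN_REMODELING
ARID2	CHROMATIN_REMODELING
EPI_CR01	CHROMATIN_REMODELING
EPI_CR02	CHROMATIN_REMODELING
EPI_CR03	CHROMATIN_REMODELING
EPI_CR04	CHROMATIN_REMODELING
EPI_CR05	CHROMATIN_REMODELING
EPI_CR06	CHROMATIN_REMODELING
EPI_CR07	CHROMATIN_REMODELING
EPI_CR08	CHROMATIN_REMODELING
EPI_CR09	CHROMATIN_REMODELING
EPI_CR10	CHROMATIN_REMODELING
EPI_CR11	CHROMATIN_REMODELING
TET2	DNA_METHYLATION_DEMETHYLATION
IDH1	DNA_METHYLATION_DEMETHYLATION
IDH2	DNA_METHYLATION_DEMETHYLATION
DNMT3A	DNA_METHYLATION_DEMETHYLATION
EPI_DM01	DNA_METHYLATION_DEMETHYLATION
EPI_DM02	DNA_METHYLATION_DEMETHYLATION
EPI_MIR01	MIRNA_PROCESSING
EPI_MIR02	MIRNA_PROCESSING
EPI_MIR03	MIRNA_PROCESSING
EPI_MIR04	MIRNA_PROCESSING
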