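table	column	description
Genes	GeneID	Stable gene identifier (text)
Genes	Gene_Symbol	Official gene symbol
Genes	Chromosome	Chromosome name as text (1-22, X, Y, MT); never numeric
Genes	Gene_Type	Gene type (protein-coding or other)
Genes	Gene_RefSeq_Status	RefSeq curation status of the gene record
Genes	Transcript_RefSeq_Statuses	Distinct RefSeq statuses of the gene's transcripts, semicolon-joined
Genes	Gene_Length_bp	Gene span length in bp (end - start + 1, 1-based inclusive)
Transcripts	GeneID	Stable gene identifier (text)
Transcripts	Gene_Symbol	Official gene symbol
Transcripts	Chromosome	Chromosome name as text
Transcripts	Gene_Type	Gene type
Transcripts	Gene_RefSeq_Status	RefSeq curation status of the gene record
Transcripts	Transcript_Accession	RefSeq mRNA accession (NM_ curated, XM_ predicted)
Transcripts	Transcript_RefSeq_Status	RefSeq curation status of the transcript
Transcripts	Transcript_Length_bp	Spliced transcript length in bp (sum of exon lengths)
Transcripts	UTR5_Length_bp	5' untranslated region length in mRNA bp (empty if non-coding)
Transcripts	CDS_Length_bp	Coding sequence length in mRNA bp, stop codon included (empty if non-coding)
Transcripts	UTR3_Length_bp	3' untranslated region length in mRNA bp (empty if non-coding)
Transcripts	Exon_Count	Number of exons in the transcript
Transcripts	Coding_Exon_Count	Number of exons with a coding portion (empty if non-coding)
Gene_Table	GeneID	Stable gene identifier (text)
Gene_Table	Gene_Symbol	Official gene symbol
Gene_Table	Gene_Type	Gene type
Gene_Table	Chromosome	Chromosome name as text
Gene_Table	Chromosome_Accession	Chromosome sequence accession (e.g. NC_000001.11)
Gene_Table	Strand	Chromosome strand (+ or -)
Gene_Table	Gene_Start	Gene span start (1-based inclusive genomic coordinate)
Gene_Table	Gene_End	Gene span end (1-based inclusive genomic coordinate)
Gene_Table	Gene_Length_bp	Gene span length in bp
Gene_Table	Transcript_Accession	RefSeq mRNA accession of the row's transcript
Gene_Table	Transcript_RefSeq_Status	RefSeq curation status of the transcript
Gene_Table	Transcript_Length_bp	Spliced transcript length in bp
Gene_Table	UTR5_Start	Genomic start of the 5' UTR bounding span (empty if no 5' UTR)
Gene_Table	UTR5_End	Genomic end of the 5' UTR bounding span (empty if no 5' UTR)
Gene_Table	UTR5_Length_bp	5' UTR length in mRNA bp (spliced; empty if non-coding)
Gene_Table	CDS_Start	Genomic coordinate of the first-to-last coding base span start (stop codon included)
Gene_Table	CDS_End	Genomic coordinate of the first-to-last coding base span end (stop codon included)
Gene_Table	CDS_Length_bp	CDS length in mRNA bp, stop codon included
Gene_Table	UTR3_Start	Genomic start of the 3' UTR bounding span (empty if no 3' UTR)
Gene_Table	UTR3_End	Genomic end of the 3' UTR bounding span (empty if no 3' UTR)
Gene_Table	UTR3_Length_bp	3' UTR length in mRNA bp (spliced; empty if non-coding)
Gene_Table	Exon_Start	Exon genomic start (stored genomically, start <= end, on both strands)
Gene_Table	Exon_End	Exon genomic end
Gene_Table	Exon_Length_bp	Exon length in bp
Gene_Table	Exon_Serial	Exon number in transcription (5'->3') order, starting at 1
Gene_Table	Coding_Start	Genomic start of this exon's coding portion (empty if none)
Gene_Table	Coding_End	Genomic end of this exon's coding portion (empty if none)
Gene_Table	Coding_Length_bp	Coding-portion length in bp (empty if none; never 0)
Gene_Table	Coding_Serial	Coding-exon number in transcription order (empty if none)
Gene_Table	Intron_Start	Genomic start of the companion intron downstream of this exon (empty on last-exon rows)
Gene_Table	Intron_End	Genomic end of the companion intron (empty on last-exon rows)
Gene_Table	Intron_Length_bp	Companion intron length in bp (empty on last-exon rows)
Gene_Table	Intron_Serial	Intron number in transcription order (empty on last-exon rows)
Gene_Table	Last_Exon	"Yes" if this exon is the last of its transcript; such rows carry no intron data
Gene_Table	Last_Coding_Exon	"Yes" if this exon carries the transcript's last coding portion
Gene_Table	Non_Redundant_Exon	"Yes—Unique" / "Yes—Merged" on one representative per identical-coordinate exon group; blank on duplicates
Gene_Table	Non_Redundant_Coding_Exon	Non-redundancy label for the coding portion, collapsed by coding-portion coordinates
Gene_Table	Non_Redundant_Intron	Non-redundancy label for the companion intron
Gene_Table	Protein_Accession	RefSeq protein accession for the transcript (empty if non-coding)
Gene_Table	Live_Status	"live" or "discontinued"
Gene_Table	Genome_Annotation_Status	"current" or "not in current annotation release"
Gene_Table	Gene_RefSeq_Status	RefSeq curation status of the gene record
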