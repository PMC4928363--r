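pfam_accession	gh_family	substrate
PF00150	GH5	cellulose
PF01341	GH6	cellulose
PF00840	GH7	cellulose
PF01270	GH8	cellulose
PF00759	GH9	cellulose
PF00331	GH10	xylan
PF00457	GH11	xylan
PF01670	GH12	cellulose
PF00704	GH18	chitin
PF00182	GH19	chitin
PF02055	GH30	xylan
PF12891	GH44	cellulose
PF02015	GH45	cellulose
PF02011	GH48	cellulose
PF03644	GH85	chitin
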