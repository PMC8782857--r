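species	unit	gene	position	strand
human	chr8	PARP10	1	-
human	chr8	PLEC	2	+
human	chr8	EPPK1	3	+
human	chr8	NRBP2	4	-
human	chr8	PUF60	5	+
cattle	chr14	PARP10	1	-
cattle	chr14	PLEC	2	+
cattle	chr14	EPPK1	3	+
cattle	chr14	NRBP2	4	-
cattle	chr14	PUF60	5	+
kiwi	scaffold_7	PARP10	1	-
kiwi	scaffold_7	PLEC	2	+
kiwi	scaffold_7	MACF1CTL	3	+
kiwi	scaffold_7	EPPK1	4	+
kiwi	scaffold_7	NRBP2	5	-
kiwi	scaffold_7	PUF60	6	+
skate	scaffold_1	EPPK1	1	+
skate	scaffold_1	NRBP2	2	-
skate	scaffold_1	PUF60	3	+
skate	scaffold_2	PLEC	1	+
skate	scaffold_2	MACF1CTL	2	+
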