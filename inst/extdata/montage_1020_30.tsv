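label	x	y	z
Fp1	0.9045084971874736146091322552820	0.2938926261462365130405771651567	0.309016994374947
Fp2	0.9045084971874736146091322552820	-0.2938926261462365130405771651567	0.309016994374947
F7	0.5590169943749474512628694355953	0.7694208842938133896538488443184	0.309016994374947
F3	0.6454163628544945519038833481318	0.4330274291738617220559603993024	0.629225686175280
Fz	0.5877852522924731371034567928291	0.0000000000000000000000000000000	0.809016994374947
F4	0.6454163628544945519038833481318	-0.4330274291738617220559603993024	0.629225686175280
F8	0.5590169943749474512628694355953	-0.7694208842938133896538488443184	0.309016994374947
FT7	0.2938926261462365685517283964145	0.9045084971874736146091322552820	0.309016994374947
FC3	0.3622911559639712120173271614476	0.5435233041098409545455183433660	0.757183951361762
FCz	0.3090169943749473957517182043375	0.0000000000000000000000000000000	0.951056516295154
FC4	0.3622911559639712120173271614476	-0.5435233041098409545455183433660	0.757183951361762
FT8	0.2938926261462365685517283964145	-0.9045084971874736146091322552820	0.309016994374947
T7	0.0000000000000000582354159244546	0.9510565162951535311819384332921	0.309016994374947
C3	0.0000000000000000359914663902998	0.5877852522924731371034567928291	0.809016994374947
Cz	0.0000000000000000000000000000000	0.0000000000000000000000000000000	1.000000000000000
C4	0.0000000000000000359914663902998	-0.5877852522924731371034567928291	0.809016994374947
T8	0.0000000000000000582354159244546	-0.9510565162951535311819384332921	0.309016994374947
TP7	-0.2938926261462364575294259338989	0.9045084971874737256314347177977	0.309016994374947
CP3	-0.3622911559639712120173271614476	0.5435233041098409545455183433660	0.757183951361762
CPz	-0.3090169943749473957517182043375	0.0000000000000000378436673043415	0.951056516295154
CP4	-0.3622911559639712120173271614476	-0.5435233041098409545455183433660	0.757183951361762
TP8	-0.2938926261462364575294259338989	-0.9045084971874737256314347177977	0.309016994374947
P7	-0.5590169943749473402405669730797	0.7694208842938133896538488443184	0.309016994374947
P3	-0.6454163628544944408815808856161	0.4330274291738617775671116305602	0.629225686175280
Pz	-0.5877852522924731371034567928291	0.0000000000000000719829327805997	0.809016994374947
P4	-0.6454163628544945519038833481318	-0.4330274291738617220559603993024	0.629225686175280
P8	-0.5590169943749473402405669730797	-0.7694208842938133896538488443184	0.309016994374947
O1	-0.9045084971874736146091322552820	0.2938926261462366240628796276724	0.309016994374947
Oz	-0.9510565162951535311819384332921	0.0000000000000001164708318489092	0.309016994374947
O2	-0.9045084971874736146091322552820	-0.2938926261462366240628796276724	0.309016994374947
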