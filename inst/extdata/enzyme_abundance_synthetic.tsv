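# Synthetic enzyme abundance table for the packaged reference instance.
# Values are plausible order-of-magnitude abundances (uM) and protein
# lengths (amino acids per functional unit) for E. coli central-metabolism
# enzymes grown on glucose; they are NOT measured data.  Reactions absent
# from this table default to the mean concentration of the others (18 uM).
reaction	conc_uM	aa_count
PTS0	10	575
PTS1	40	85
PTS2	25	169
PTS3	20	477
PTS4	15	477
PGI	55	549
PFK	30	320
PFKB	2	309
FBP	8	332
FBA	90	359
TPI	60	255
GDH	180	331
PGK	110	387
GPM	70	250
ENO	130	432
PYK	45	470
PPS	12	792
PDH	50	2200
ZWF	15	491
PGL	10	331
GND	35	468
RPE	15	225
RPI	20	219
TKT1	40	663
TAL	25	317
TKT2	30	663
EDD	5	603
EDA	8	213
PPC	20	883
PCK	15	540
MAE	6	565
GLT	40	427
ACN	30	891
ICD	60	416
AKGDH	35	2026
SUCOAS	30	672
SDH	25	1177
SQR	25	1177
FUMA	30	548
MDH	70	312
MQO	4	548
FRD	3	1073
ICL	10	434
MALS	8	533
PTA	25	714
ACK	20	400
ACS	10	652
POXB	5	572
NDHI	20	1500
NDHII	25	434
CYTBO	30	1324
ATP_SYN	45	1756
ADK	35	214
CYA	3	848
DOS	3	799
PNT	15	1014
ATP_NGAM	18	500
GROWTH	18	500
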