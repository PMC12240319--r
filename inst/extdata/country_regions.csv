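country,region
US,north_america
CA,north_america
MX,north_america
PR,north_america
GT,north_america
CU,north_america
DO,north_america
PA,north_america
CR,north_america
JM,north_america
AR,south_america
BO,south_america
BR,south_america
CL,south_america
CO,south_america
EC,south_america
PE,south_america
PY,south_america
UY,south_america
VE,south_america
AT,europe
BE,europe
BG,europe
CH,europe
CZ,europe
DE,europe
DK,europe
EE,europe
ES,europe
FI,europe
FR,europe
GB,europe
GR,europe
HR,europe
HU,europe
IE,europe
IS,europe
IT,europe
LT,europe
LU,europe
LV,europe
NL,europe
NO,europe
PL,europe
PT,europe
RO,europe
RS,europe
RU,europe
SE,europe
SI,europe
SK,europe
TR,europe
UA,europe
AE,asia
BD,asia
CN,asia
HK,asia
ID,asia
IL,asia
IN,asia
IQ,asia
IR,asia
JP,asia
KR,asia
KZ,asia
LK,asia
MY,asia
PH,asia
PK,asia
SA,asia
SG,asia
TH,asia
TW,asia
VN,asia
AU,oceania
FJ,oceania
NZ,oceania
PG,oceania
DZ,africa
EG,africa
ET,africa
GH,africa
KE,africa
MA,africa
NG,africa
TN,africa
TZ,africa
UG,africa
ZA,africa
ZM,africa
ZW,africa
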