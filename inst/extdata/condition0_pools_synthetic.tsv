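text	role
roll	word
fish	word
hand	word
lamp	word
desk	word
ring	word
song	word
wind	word
bell	word
door	word
moon	word
star	word
fork	word
leaf	word
book	word
rain	word
snow	word
wall	word
roof	word
girl	word
king	word
duck	word
frog	word
goat	word
wolf	word
lion	word
bear	word
crab	word
tent	word
boat	word
card	word
coin	word
drum	word
flag	word
gold	word
hill	word
iron	word
kick	word
lock	word
mask	word
nest	word
oven	word
pond	word
rock	word
sand	word
tank	word
vest	word
worm	word
yard	word
barn	word
bank	word
cart	word
dish	word
exit	word
fist	word
gift	word
hunt	word
inch	word
jail	word
lamb	word
mint	word
nail	word
raft	word
sail	word
tail	word
vein	word
wing	word
yarn	word
bolt	word
cork	word
dust	word
fern	word
tmgv	consonant_string
wkrs	consonant_string
rwsh	consonant_string
dqxk	consonant_string
srjq	consonant_string
rzwc	consonant_string
vdzr	consonant_string
nqkj	consonant_string
gvzq	consonant_string
wlvz	consonant_string
dzsd	consonant_string
npxv	consonant_string
fglr	consonant_string
lshd	consonant_string
gswq	consonant_string
vlsg	consonant_string
vfxz	consonant_string
kknj	consonant_string
bdbc	consonant_string
jmts	consonant_string
bbvc	consonant_string
bbmz	consonant_string
dsnf	consonant_string
ggkd	consonant_string
zknv	consonant_string
wndr	consonant_string
thgn	consonant_string
svdn	consonant_string
tcmx	consonant_string
swgd	consonant_string
ctcb	consonant_string
sdsw	consonant_string
qbfd	consonant_string
jjnm	consonant_string
rtrt	consonant_string
snlp	consonant_string
mghq	consonant_string
nhkr	consonant_string
tjqz	consonant_string
lrlz	consonant_string
svvr	consonant_string
kkzq	consonant_string
thbd	consonant_string
xpgn	consonant_string
nbdl	consonant_string
dxnf	consonant_string
xffb	consonant_string
vvfs	consonant_string
xxtd	consonant_string
gztx	consonant_string
fmrw	consonant_string
qdjw	consonant_string
gjdw	consonant_string
cklg	consonant_string
bcdl	consonant_string
plxg	consonant_string
xpfn	consonant_string
xtqg	consonant_string
kxcr	consonant_string
qznf	consonant_string
fmhj	consonant_string
phnb	consonant_string
gwzs	consonant_string
jvtq	consonant_string
mrrt	consonant_string
qxgr	consonant_string
tprp	consonant_string
ntjm	consonant_string
hbqz	consonant_string
frdg	consonant_string
zqtr	consonant_string
nhtf	consonant_string
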