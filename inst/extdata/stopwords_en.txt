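a
about
above
after
again
against
ain
all
also
although
am
among
an
and
any
are
aren
as
at
be
because
been
before
being
below
between
both
but
by
can
cannot
could
couldn
d
did
didn
do
does
doesn
doing
don
down
during
each
few
for
from
further
had
hadn
has
hasn
have
haven
having
he
her
here
hers
herself
him
himself
his
how
however
i
if
in
into
is
isn
it
its
itself
just
let
ll
m
may
me
might
mightn
more
most
must
mustn
my
myself
needn
no
nor
not
now
o
of
off
on
once
only
onto
or
other
ought
our
ours
ourselves
out
over
own
per
re
s
same
shall
shan
she
should
shouldn
so
some
such
t
than
that
the
their
theirs
them
themselves
then
there
therefore
these
they
this
those
though
through
thus
to
too
under
until
up
upon
ve
very
via
was
wasn
we
were
weren
what
when
where
which
while
who
whom
why
will
with
within
without
won
would
wouldn
y
you
your
yours
yourself
yourselves
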